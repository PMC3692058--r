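test_that("configuration defaults match the documented server defaults", {
  cfg <- run_config()
  expect_equal(cfg$range$t1, 32L)
  expect_equal(cfg$range$t2, 39L)
  expect_equal(cfg$threshold_sd, 3)
  expect_equal(cfg$dbscan$eps, 11L)
  expect_equal(cfg$dbscan$min_pts, 5L)
  expect_false(cfg$fold$no_gu)
  expect_true(cfg$is_coding)
  expect_equal(cfg$n_mutants, 100L)
})

test_that("a homopolymer yields an empty significant set and no clusters", {
  run <- run_single(rna_sequence(strrep("A", 80), id = "polyA"))
  expect_equal(run$general_info$n_significant, 0L)
  expect_equal(run$general_info$n_clusters, 0L)
  expect_length(run$clusters, 0L)
  dir <- tempfile("run")
  write_run_outputs(run, dir)
  summary <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_true(summary$sequences[[1]]$no_clusters_identified)
})

test_that("the melting fixture yields a cluster covering the designed element", {
  run <- run_single(make_fixture("melting-hairpin"))
  expect_equal(run$positions, c(26:28, 33:35))
  expect_length(run$clusters, 1L)
  expect_lte(run$clusters[[1]]$start, 26L)
  expect_gte(run$clusters[[1]]$end, 35L)
  gi <- run$general_info
  expect_equal(gi$signif_neg + gi$signif_pos, gi$n_significant)
  # cluster onset = first elevated temperature at which any member is flagged
  flagged_temps <- which(rowSums(
    run$sig$flags[, run$clusters[[1]]$members, drop = FALSE]) > 0)
  expect_equal(run$cluster_info$onset,
               as.integer(rownames(run$sig$flags)[min(flagged_temps)]))
})

test_that("pair runs on identical sequences skip the mutant stage", {
  s <- make_fixture("melting-hairpin")
  s$is_coding <- FALSE
  pr <- run_pair(s, s, run_config(n_mutants = 5L))
  expect_match(pr$mutant_note, "identical")
  expect_null(pr$cluster_tests)
  expect_length(pr$specific_clusters$specific_a, 0L)

  skip_cfg <- run_config(skip_mutants = TRUE)
  fx <- make_fixture("pair-with-specific-cluster")
  pr2 <- run_pair(fx$a, fx$b, skip_cfg)
  expect_match(pr2$mutant_note, "skipped")
  expect_null(pr2$cluster_tests)
  dir <- tempfile("pairskip")
  write_run_outputs(pr2, dir)
  expect_false(file.exists(file.path(dir, "cluster_tests.tsv")))
  expect_false(file.exists(file.path(dir, "mutants.fasta")))
  expect_true(file.exists(file.path(dir, "comparison.txt")))
})

test_that("infeasible mutagenesis downgrades to a warning with tests skipped", {
  a <- rna_sequence("AUGUGGAUGUGG", id = "a", is_coding = TRUE)
  b <- rna_sequence("AUGUGGAUGUGC", id = "b", is_coding = TRUE)
  expect_warning(pr <- run_pair(a, b, run_config(n_mutants = 3L)),
                 "infeasible")
  expect_match(pr$mutant_note, "infeasible")
  expect_null(pr$cluster_tests)
})

test_that("pair outputs include every defined table", {
  fx <- make_fixture("pair-with-specific-cluster")
  cfg <- run_config(n_mutants = 8L, seed = 31L)
  pr <- run_pair(fx$a, fx$b, cfg)
  dir <- tempfile("pair")
  write_run_outputs(pr, dir)
  for (f in c("summary.json", "general_info.tsv", "comparison.txt",
              "comparison.html", "cluster_tests.tsv", "mutants.fasta",
              "clusters_fixture_a.tsv", "clusters_fixture_b.tsv",
              "histogram_fixture_a.tsv", "histogram_fixture_b.tsv",
              "density_fixture_a.tsv", "density_fixture_b.tsv",
              "scatter_fixture_a.tsv", "scatter_fixture_b.tsv"))
    expect_true(file.exists(file.path(dir, f)), info = f)
  hist_a <- read.delim(file.path(dir, "histogram_fixture_a.tsv"))
  expect_equal(nrow(hist_a), 7L * 120L)
  gi <- read.delim(file.path(dir, "general_info.tsv"))
  expect_equal(gi$signif_neg + gi$signif_pos, gi$n_significant)
  tests <- read.delim(file.path(dir, "cluster_tests.tsv"))
  expect_equal(nrow(tests), nrow(pr$cluster_tests))
})

test_that("fixtures are reproducible and mutant analysis respects the seed", {
  f1 <- make_fixture("pair-with-specific-cluster", seed = 1L)
  f2 <- make_fixture("pair-with-specific-cluster", seed = 1L)
  expect_identical(f1, f2)
  expect_identical(make_fixture("stable-hairpin"),
                   make_fixture("stable-hairpin"))
})
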