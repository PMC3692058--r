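# build significant_positions objects from explicit per-temperature
# profiles via an injected provider
sig_from_profiles <- function(profiles, L, k = 3) {
  s <- rna_sequence(strrep("A", L))
  temps <- as.integer(names(profiles))
  ds <- diff_dataset(scan_temperatures(
    s, temperature_range(min(temps), max(temps)),
    backend = table_backend(profiles)))
  significant_positions(ds, k)
}

spike_profiles <- function(L, spikes) {
  # spikes: named list "t" -> positions raised to 0.9
  setNames(lapply(32:39, function(t) {
    p <- rep(0, L)
    hit <- spikes[[as.character(t)]]
    if (!is.null(hit)) p[hit] <- 0.9
    p
  }), 32:39)
}

test_that("positions are classified into shared and sequence-specific sets", {
  L <- 40L
  sig_a <- sig_from_profiles(spike_profiles(L, list(`39` = c(5L, 6L))), L)
  sig_b <- sig_from_profiles(spike_profiles(L, list(`39` = c(6L, 7L))), L)
  cls <- classify_positions(sig_a, sig_b)
  expect_equal(cls$shared[["39"]], 6L)
  expect_equal(cls$specific_a[["39"]], 5L)
  expect_equal(cls$specific_b[["39"]], 7L)

  # identical inputs: everything shared
  self <- classify_positions(sig_a, sig_a)
  expect_equal(self$shared[["39"]], c(5L, 6L))
  expect_length(self$specific_a[["39"]], 0L)

  # empty second analysis: everything specific to a
  sig_none <- sig_from_profiles(spike_profiles(L, list()), L)
  alone <- classify_positions(sig_a, sig_none)
  expect_equal(alone$specific_a[["39"]], c(5L, 6L))
  expect_length(alone$shared[["39"]], 0L)
})

test_that("classification is symmetric and partitions the significant set", {
  L <- 60L
  set.seed(41)
  mk <- function() {
    spikes <- list()
    for (t in sample(33:39, 3))
      spikes[[as.character(t)]] <- sort(sample.int(L, 6))
    sig_from_profiles(spike_profiles(L, spikes), L)
  }
  a <- mk(); b <- mk()
  ab <- classify_positions(a, b)
  ba <- classify_positions(b, a)
  expect_identical(ab$shared, ba$shared)
  expect_identical(ab$specific_a, ba$specific_b)
  for (t in names(ab$shared)) {
    expect_length(intersect(ab$shared[[t]], ab$specific_a[[t]]), 0L)
    expect_equal(sort(c(ab$shared[[t]], ab$specific_a[[t]])),
                 sort(a$per_temperature[[t]]))
  }
})

test_that("cluster specificity uses span overlap of at least one position", {
  ca <- dbscan_1d(100:120)
  expect_length(ca, 1L)
  # no clusters on the other side: specific
  sp <- specific_clusters(ca, list())
  expect_length(sp$specific_a, 1L)
  # sharing exactly position 120: neither specific
  cb_touch <- dbscan_1d(120:140)
  sp2 <- specific_clusters(ca, cb_touch)
  expect_length(sp2$specific_a, 0L)
  expect_length(sp2$specific_b, 0L)
  # adjacent but disjoint spans: both specific
  cb_adj <- dbscan_1d(121:140)
  sp3 <- specific_clusters(ca, cb_adj)
  expect_length(sp3$specific_a, 1L)
  expect_length(sp3$specific_b, 1L)
})

test_that("onset temperature is the lowest flagged elevated temperature", {
  L <- 30L
  spikes <- list(`36` = 10L, `37` = 10L, `38` = 10L,
                 `39` = c(10L, 12L))
  sig <- sig_from_profiles(spike_profiles(L, spikes), L)
  expect_equal(onset_temperature(sig, 10L), 36L)
  expect_equal(onset_temperature(sig, 12L), 39L)   # top only
  expect_true(is.na(onset_temperature(sig, 5L)))
  expect_error(onset_temperature(sig, 99L), "outside")

  cl <- dbscan_1d(8:12, dbscan_params(eps = 3, min_pts = 2))[[1]]
  expect_equal(cluster_onset(sig, cl), 36L)
})

test_that("comparison rendering marks shared, specific and substitutions", {
  fx <- make_fixture("pair-with-specific-cluster")
  cfg <- run_config(skip_mutants = TRUE)
  ra <- run_single(fx$a, cfg)
  rb <- run_single(fx$b, cfg)
  txt <- render_comparison(fx$a, fx$b, ra$sig, rb$sig)
  expect_match(txt, "o")                       # sequence-specific marks
  lines <- strsplit(txt, "\n")[[1]]
  match_lines <- grep("^match", lines, value = TRUE)
  expect_equal(sum(vapply(strsplit(match_lines, ""), function(x)
    sum(x == "-"), integer(1))), 1L)           # exactly one substitution
  html <- render_comparison(fx$a, fx$b, ra$sig, rb$sig, format = "html")
  expect_match(html, "color:orange")
})
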