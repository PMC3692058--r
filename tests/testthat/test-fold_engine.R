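test_that("structure enumeration matches hand counts", {
  expect_length(enumerate_structures(rna_sequence("AAAA")), 1L)  # empty only
  gs <- enumerate_structures(rna_sequence("GAAAC"))
  expect_length(gs, 2L)                                 # empty + G1-C5
  expect_equal(gs[[2]], matrix(c(1L, 5L), 1, 2, dimnames = list(NULL, c("i", "j"))))
  # AGAAACU legal pairs: (1,7) A-U, (2,6) G-C, (2,7) G-U, (3,7) A-U;
  # compatible doubles: {(1,7),(2,6)} only -> 1 + 4 + 1 structures
  expect_length(enumerate_structures(rna_sequence("AGAAACU")), 6L)
  expect_error(enumerate_structures(random_rna(30)), "too long")
})

test_that("reference matrix equals Boltzmann-weighted enumeration", {
  set.seed(101)
  worst <- 0
  for (r in 1:12) {
    s <- random_rna(sample(5:16, 1))
    for (t in c(10L, 37L, 90L)) {
      for (opts in list(fold_options(), fold_options(no_gu = TRUE))) {
        dev <- max(abs(reference_pair_matrix(s, t, opts) -
                         enumerated_pair_matrix(s, t, opts)))
        worst <- max(worst, dev)
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("paired vector equals the pair-matrix row sums and lies in [0,1]", {
  set.seed(5)
  for (r in 1:6) {
    s <- random_rna(sample(10:40, 1))
    P <- reference_pair_matrix(s, 37)
    p <- pairing_probabilities(s, 37)
    expect_equal(p, unname(rowSums(P)), tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(P, t(P))
    expect_true(all(diag(P) == 0))
    n <- nrow(P)
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (abs(i - j) < 4) expect_identical(P[i, j], 0)
    expect_true(all(rowSums(P) <= 1 + 1e-9))
  }
})

test_that("sequences without legal pairs give all-zero probabilities", {
  expect_equal(pairing_probabilities(rna_sequence("AAAAAAAAAA"), 37),
               rep(0, 10))
  expect_equal(pairing_probabilities(rna_sequence("AAAAAAAAAA"), 90),
               rep(0, 10))
  # 4-mers cannot satisfy the minimum hairpin loop
  expect_true(all(reference_pair_matrix(rna_sequence("GAAC"), 37) == 0))
})

test_that("GU options restrict wobble pairing as documented", {
  gu_only <- rna_sequence("GGGGGUUUUU")
  expect_equal(pairing_probabilities(gu_only, 37, fold_options(no_gu = TRUE)),
               rep(0, 10))
  # no_gu zeroes every G-U cell of the matrix even when other pairs remain
  s <- rna_sequence("GGGGAAAAUUUUCCCC")
  P <- reference_pair_matrix(s, 37, fold_options(no_gu = TRUE))
  ch <- strsplit(s$residues, "")[[1]]
  for (i in seq_along(ch)) for (j in seq_along(ch)) {
    pr <- paste0(ch[i], ch[j])
    if (pr %in% c("GU", "UG")) expect_identical(P[i, j], 0)
  }
  # reference-engine no_close_gu needs a canonical pair to stack on, so a
  # wobble-only sequence stays fully unpaired
  expect_equal(pairing_probabilities(gu_only, 37,
                                     fold_options(no_close_gu = TRUE)),
               rep(0, 10))
  # enumeration oracle applies the exact rule: a lone G-U pair is dropped
  expect_length(enumerate_structures(rna_sequence("GAAAU")), 2L)
  expect_length(enumerate_structures(rna_sequence("GAAAU"),
                                     fold_options(no_close_gu = TRUE)), 1L)
})

test_that("an A,U-rich helix melts: total pairing falls with temperature", {
  s <- make_fixture("melting-hairpin")
  cold <- sum(reference_pair_matrix(s, 10))
  hot <- sum(reference_pair_matrix(s, 90))
  expect_lt(hot, cold)
  # and pointwise across the default range for the designed element
  p32 <- pairing_probabilities(s, 32)
  p39 <- pairing_probabilities(s, 39)
  elem <- c(26:28, 33:35)
  expect_true(all(p39[elem] < p32[elem]))
})

test_that("reference-engine probabilities vary continuously with temperature", {
  s <- make_fixture("melting-hairpin")
  prev <- pairing_probabilities(s, 30)
  for (t in 31:45) {
    cur <- pairing_probabilities(s, t)
    expect_lt(max(abs(cur - prev)), 0.06)
    prev <- cur
  }
})

test_that("backend registry validates providers and rejects unknown names", {
  s <- rna_sequence("ACGUACGU")
  expect_error(pairing_probabilities(s, 37, backend = "no-such-backend"),
               "unknown fold backend")
  register_fold_backend("short", function(seq, t, opts) 0.5)
  on.exit(register_fold_backend("short", NULL))
  expect_error(pairing_probabilities(s, 37, backend = "short"),
               "backend returned")
  expect_error(pairing_probabilities(s, 37, backend = constant_backend(2)),
               "outside")
  expect_equal(pairing_probabilities(s, 37, backend = constant_backend(0.25)),
               rep(0.25, 8))
})

test_that("the vienna adapter reads RNAfold pair probabilities", {
  s <- rna_sequence("GGGGGAAAACCCCC")
  p <- pairing_probabilities(s, 37, backend = "vienna")
  expect_length(p, 14L)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(min(p[c(1:5, 10:14)]), 0.5)   # strong G-C stem
  expect_equal(pairing_probabilities(rna_sequence("GGGGGUUUUU"), 37,
                                     fold_options(no_gu = TRUE),
                                     backend = "vienna"),
               rep(0, 10))
  expect_match(vienna_version(), "RNAfold")
})
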