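test_that("scan shape follows the temperature range", {
  s <- rna_sequence(strrep("A", 40))
  prof <- scan_temperatures(s, temperature_range(10, 11),
                            backend = constant_backend(0.5))
  expect_equal(dim(prof$matrix), c(2L, 40L))
  expect_equal(prof$temperatures, 10:11)

  prof8 <- scan_temperatures(s, temperature_range(32, 39),
                             backend = constant_backend(0.5))
  expect_equal(dim(prof8$matrix), c(8L, 40L))
  # a temperature-independent provider yields identical rows
  expect_true(all(apply(prof8$matrix, 2, function(col) all(col == col[1]))))
})

test_that("combined difference set has (t2 - t1) x L values; d = p_t - p_t1", {
  L <- 50L
  s <- rna_sequence(strrep("A", L))
  profiles <- setNames(lapply(32:39, function(t) rep((t - 32) / 100, L)),
                       32:39)
  ds <- diff_dataset(scan_temperatures(s, temperature_range(32, 39),
                                       backend = table_backend(profiles)))
  expect_length(ds$combined, 7L * L)
  expect_equal(nrow(ds$diffs), 7L)
  # rising profile gives positive differences with the documented direction
  expect_equal(unname(ds$diffs[7, 1]), 0.07)
  expect_equal(unname(ds$diffs[1, 1]), 0.01)
  expect_true(all(ds$combined >= -1 & ds$combined <= 1))

  const <- diff_dataset(scan_temperatures(s, temperature_range(32, 39),
                                          backend = constant_backend(0.3)))
  expect_true(all(const$combined == 0))
  expect_equal(const$mean, 0)
  expect_equal(const$sd, 0)
  single <- structure(list(temperatures = 32L,
                           matrix = matrix(0.5, 1, L,
                                           dimnames = list("32", NULL))),
                      class = "pairing_profile")
  expect_error(diff_dataset(single), "at least two")
})

test_that("population SD over the combined vector is used", {
  L <- 10L
  s <- rna_sequence(strrep("A", L))
  profiles <- setNames(lapply(32:34, function(t)
    if (t == 34) c(0.5, rep(0, L - 1)) else rep(0, L)), 32:34)
  ds <- diff_dataset(scan_temperatures(s, temperature_range(32, 34),
                                       backend = table_backend(profiles)))
  m <- mean(ds$combined)
  expect_equal(ds$sd, sqrt(mean((ds$combined - m)^2)))
  expect_false(isTRUE(all.equal(ds$sd, stats::sd(ds$combined))))
})

test_that("a single outlier among 7000 values is flagged at k = 3 only", {
  L <- 1000L
  s <- rna_sequence(strrep("A", L))
  profiles <- setNames(lapply(32:39, function(t) {
    p <- rep(0, L)
    if (t == 39L) p[417] <- 0.5
    p
  }), 32:39)
  ds <- diff_dataset(scan_temperatures(s, temperature_range(32, 39),
                                       backend = table_backend(profiles)))
  expect_length(ds$combined, 7000L)
  expect_equal(ds$mean, 0.5 / 7000)
  sig <- significant_positions(ds, 3)
  expect_equal(unname(which(sig$flags, arr.ind = TRUE)),
               matrix(c(7L, 417L), 1, 2))
  expect_equal(sig$per_temperature[["39"]], 417L)
  expect_equal(unname(sig$increase_set), 417L)
  expect_length(sig$decrease_set, 0L)
  # absurdly high threshold flags nothing
  none <- significant_positions(ds, 1000)
  expect_false(any(none$flags))
})

test_that("sd = 0 yields no significant positions", {
  s <- rna_sequence(strrep("A", 30))
  ds <- diff_dataset(scan_temperatures(s, temperature_range(32, 39),
                                       backend = constant_backend(0.7)))
  sig <- significant_positions(ds)
  expect_false(any(sig$flags))
  expect_length(sig$increase_set, 0L)
  expect_length(sig$decrease_set, 0L)
})

test_that("raising the threshold never adds significant positions", {
  L <- 60L
  s <- rna_sequence(strrep("A", L))
  set.seed(23)
  profiles <- setNames(lapply(32:39, function(t) runif(L, 0, 1)), 32:39)
  ds <- diff_dataset(scan_temperatures(s, temperature_range(32, 39),
                                       backend = table_backend(profiles)))
  prev <- NULL
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    cur <- which(significant_positions(ds, k)$flags)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("sign bookkeeping splits increase and decrease sets at the top row", {
  L <- 20L
  s <- rna_sequence(strrep("A", L))
  profiles <- setNames(lapply(32:39, function(t) {
    p <- rep(0.5, L)
    if (t == 39L) { p[3] <- 0.9; p[11] <- 0.1 }
    p
  }), 32:39)
  ds <- diff_dataset(scan_temperatures(s, temperature_range(32, 39),
                                       backend = table_backend(profiles)))
  sig <- significant_positions(ds, 3)
  expect_equal(unname(sig$increase_set), 3L)
  expect_equal(unname(sig$decrease_set), 11L)
  top <- sort(which(sig$flags[nrow(sig$flags), ]))
  expect_equal(sort(unname(c(sig$increase_set, sig$decrease_set))), top)
})

test_that("scans with a deterministic backend are bit-identical", {
  s <- make_fixture("melting-hairpin")
  p1 <- scan_temperatures(s, temperature_range(32, 39))
  p2 <- scan_temperatures(s, temperature_range(32, 39))
  expect_identical(p1, p2)
})
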