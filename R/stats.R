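#' @title Cluster-specificity statistics
#' @name cluster_stats
#' @description For every sequence-specific cluster, counts how often a
#'   cluster overlapping it (by at least one position) recurs among the
#'   in-silico mutants and performs a one-sided exact binomial test. For a
#'   cluster present in the first sequence but absent from the second, the
#'   null hypothesis is that the probability of observing the cluster is
#'   below 95 percent, so a small p-value indicates the cluster is
#'   unlikely to disappear by chance; for a cluster present only in the
#'   second sequence, the null is that its occurrence probability among
#'   the mutants is at least 5 percent, so a small p-value indicates it is
#'   unlikely to appear by chance. Both tests are computed at the null
#'   boundary (p0 = 0.95 and 0.05 respectively).
NULL

check_kn <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || k != as.integer(k) ||
      n != as.integer(n) || n < 1L || k < 0L || k > n)
    stop("require integers 0 <= k <= n, n >= 1", call. = FALSE)
  c(as.integer(k), as.integer(n))
}

#' Count mutants whose clusters overlap a target cluster
#'
#' @param target an `rna_cluster` (a sequence-specific cluster).
#' @param mutant_cluster_lists list with one cluster list per mutant, each
#'   produced by the same pipeline parameters as the originals.
#' @return List with `k` (mutants having at least one cluster whose span
#'   intersects the target span in at least one position) and `n` (number
#'   of mutants).
#' @export
overlap_count <- function(target, mutant_cluster_lists) {
  if (!length(mutant_cluster_lists))
    stop("no mutants supplied (n = 0)", call. = FALSE)
  hits <- vapply(mutant_cluster_lists, function(cls)
    any(vapply(cls, function(cl) span_overlaps(target, cl), logical(1))),
    logical(1))
  list(k = sum(hits), n = length(hits))
}

#' One-sided binomial test for a disappearing cluster
#'
#' Upper-tail exact binomial p-value at the null boundary p0 = 0.95:
#' the probability of observing `k` or more overlap successes among `n`
#' mutants when the cluster's persistence probability is 0.95. A small
#' p-value supports persistence above 95 percent, i.e. the cluster is
#' unlikely to disappear in the second sequence by chance.
#'
#' @param k number of mutants overlapping the cluster.
#' @param n number of mutants.
#' @return List with `p_value`, `frequency` (k/n), `ci_95`
#'   (Clopper-Pearson), `null_boundary` (0.95) and `direction`
#'   (`"disappear"`).
#' @export
test_cluster_disappear <- function(k, n) {
  kn <- check_kn(k, n)
  p <- pbinom(kn[1] - 1L, kn[2], 0.95, lower.tail = FALSE)
  list(k = kn[1], n = kn[2], frequency = kn[1] / kn[2], p_value = p,
       ci_95 = binomial_ci(kn[1], kn[2]), null_boundary = 0.95,
       direction = "disappear")
}

#' One-sided binomial test for an appearing cluster
#'
#' Lower-tail exact binomial p-value at the null boundary p0 = 0.05: the
#' probability of observing `k` or fewer overlaps among `n` mutants when
#' the cluster's occurrence probability is 0.05. A small p-value
#' indicates the cluster is unlikely to appear in the second sequence by
#' chance.
#'
#' @inheritParams test_cluster_disappear
#' @return List as in [test_cluster_disappear()], with `null_boundary`
#'   0.05 and `direction` `"appear"`.
#' @export
test_cluster_appear <- function(k, n) {
  kn <- check_kn(k, n)
  p <- pbinom(kn[1], kn[2], 0.05, lower.tail = TRUE)
  list(k = kn[1], n = kn[2], frequency = kn[1] / kn[2], p_value = p,
       ci_95 = binomial_ci(kn[1], kn[2]), null_boundary = 0.05,
       direction = "appear")
}

#' Exact 95 percent confidence interval for an overlap frequency
#'
#' Two-sided Clopper-Pearson interval for the probability underlying
#' `k` successes out of `n`.
#'
#' @inheritParams test_cluster_disappear
#' @return Numeric vector `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n) {
  kn <- check_kn(k, n)
  ci <- binom.test(kn[1], kn[2])$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Statistical table for all sequence-specific clusters
#'
#' Applies the appropriate one-sided test to every sequence-specific
#' cluster of both sequences against one mutant-derived cluster ensemble
#' (the mutants are derivatives of the first sequence). Clusters specific
#' to the first sequence are tested for disappearance; clusters specific
#' to the second for appearance.
#'
#' @param specific_a,specific_b lists of sequence-specific `rna_cluster`
#'   objects (see [specific_clusters()]).
#' @param mutant_cluster_lists list of cluster lists, one per mutant.
#' @return data.frame with columns `sequence`, `start`, `end`, `direction`,
#'   `k`, `n`, `frequency`, `p_value`, `ci_low`, `ci_high`. Zero rows when
#'   there are no specific clusters.
#' @export
cluster_test_table <- function(specific_a, specific_b, mutant_cluster_lists) {
  rows <- list()
  add <- function(cl, which_seq, direction) {
    oc <- overlap_count(cl, mutant_cluster_lists)
    res <- if (direction == "disappear")
      test_cluster_disappear(oc$k, oc$n) else test_cluster_appear(oc$k, oc$n)
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = which_seq, start = cl$start, end = cl$end,
      direction = direction, k = res$k, n = res$n,
      frequency = res$frequency, p_value = res$p_value,
      ci_low = res$ci_95[["lower"]], ci_high = res$ci_95[["upper"]])
  }
  for (cl in specific_a) add(cl, "A", "disappear")
  for (cl in specific_b) add(cl, "B", "appear")
  if (!length(rows))
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      k = integer(0), n = integer(0), frequency = numeric(0),
                      p_value = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  out <- do.call(rbind, rows)
  if (nrow(out) > 1L)
    message(nrow(out), " sequence-specific clusters tested; p-values are ",
            "reported per cluster without multiple-testing correction")
  out
}
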