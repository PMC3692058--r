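#' @title Temperature scan, difference data set and significant positions
#' @name temp_scan
#' @description Scans a sequence at every integer temperature in the range,
#'   assembles per-nucleotide probability differences against the base
#'   temperature into one combined data set, and flags the positions whose
#'   difference lies further than k standard deviations from the data-set
#'   mean (k = 3 by default).
NULL

#' Scan pairing probabilities across a temperature range
#'
#' Computes the paired-state probability vector at each integer temperature
#' `t1..t2` and stacks them into a profile matrix.
#'
#' @param seq an [rna_sequence()].
#' @param range a [temperature_range()].
#' @param opts [fold_options()].
#' @param backend backend name or provider function (see
#'   [pairing_probabilities()]).
#' @return An object of class `pairing_profile`: list with `temperatures`
#'   and `matrix` ((t2 - t1 + 1) x L, rows named by temperature).
#' @export
scan_temperatures <- function(seq, range = temperature_range(),
                              opts = fold_options(), backend = "reference") {
  stopifnot(inherits(seq, "rna_sequence"), inherits(range, "temperature_range"))
  n <- nchar(seq$residues)
  mat <- matrix(NA_real_, length(range$temperatures), n,
                dimnames = list(range$temperatures, NULL))
  for (idx in seq_along(range$temperatures)) {
    t <- range$temperatures[idx]
    p <- tryCatch(pairing_probabilities(seq, t, opts, backend),
                  error = function(e)
                    stop("temperature scan failed at ", t, " degrees C: ",
                         conditionMessage(e), call. = FALSE))
    mat[idx, ] <- p
  }
  structure(list(temperatures = range$temperatures, matrix = mat),
            class = "pairing_profile")
}

#' @export
print.pairing_profile <- function(x, ...) {
  cat(sprintf("<pairing_profile> %d temperatures (%d..%d degrees C) x %d nt\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), ncol(x$matrix)))
  invisible(x)
}

#' Combined probability-difference data set
#'
#' For every elevated temperature t in (t1, t2] and position i, the
#' difference d(t, i) = p_t(i) - p_t1(i) is computed; all (t2 - t1) * L
#' values are combined into one data set whose mean and standard deviation
#' define the significance threshold. For a 1000-nt sequence scanned over
#' 32--39 degrees C the combined set holds 7000 values. The standard
#' deviation uses the population convention (divisor n), the combined set
#' being the complete population of computed differences.
#'
#' @param profile a `pairing_profile` from [scan_temperatures()].
#' @return An object of class `diff_dataset`: list with `diffs`
#'   ((t2 - t1) x L matrix, rows named by elevated temperature),
#'   `combined` (flattened vector), `mean`, `sd`, `t1` and `temperatures`
#'   (the elevated temperatures).
#' @export
diff_dataset <- function(profile) {
  stopifnot(inherits(profile, "pairing_profile"))
  if (length(profile$temperatures) < 2L)
    stop("the profile must cover at least two temperatures", call. = FALSE)
  base <- profile$matrix[1L, ]
  diffs <- profile$matrix[-1L, , drop = FALSE] -
    matrix(base, nrow(profile$matrix) - 1L, length(base), byrow = TRUE)
  combined <- as.vector(t(diffs))  # temperature-major, position within
  m <- mean(combined)
  s <- sqrt(mean((combined - m)^2))
  structure(list(diffs = diffs, combined = combined, mean = m, sd = s,
                 t1 = profile$temperatures[1L],
                 temperatures = profile$temperatures[-1L]),
            class = "diff_dataset")
}

#' @export
print.diff_dataset <- function(x, ...) {
  cat(sprintf(
    "<diff_dataset> %d values (%d elevated temperatures x %d nt), mean %.3g, sd %.3g\n",
    length(x$combined), nrow(x$diffs), ncol(x$diffs), x$mean, x$sd))
  invisible(x)
}

#' Flag the most temperature-sensitive positions
#'
#' A cell (t, i) is significant when its difference d(t, i) lies further
#' than `k` standard deviations from the mean of the combined data set.
#' When the data set is perfectly temperature-insensitive (sd = 0) no
#' position is significant.
#'
#' @param ds a `diff_dataset`.
#' @param k significance threshold in standard deviations (default 3).
#' @return An object of class `significant_positions`: list with
#'   `threshold_sd`, `flags` (logical matrix, same shape as `ds$diffs`),
#'   `per_temperature` (named list of 1-based position vectors),
#'   `top_temperature`, `increase_set` / `decrease_set` (positions whose
#'   top-difference d is positive / negative among the significant ones),
#'   and the `mean` / `sd` used.
#' @export
significant_positions <- function(ds, k = 3) {
  stopifnot(inherits(ds, "diff_dataset"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("the threshold k must be a positive number", call. = FALSE)
  if (ds$sd > 0) {
    flags <- abs(ds$diffs - ds$mean) > k * ds$sd
  } else {
    flags <- matrix(FALSE, nrow(ds$diffs), ncol(ds$diffs))
  }
  dimnames(flags) <- dimnames(ds$diffs)
  per_t <- lapply(seq_len(nrow(flags)), function(r) which(flags[r, ]))
  names(per_t) <- rownames(ds$diffs)
  top <- nrow(flags)
  top_sig <- which(flags[top, ])
  d_top <- ds$diffs[top, ]
  structure(list(threshold_sd = k, flags = flags, per_temperature = per_t,
                 top_temperature = ds$temperatures[top],
                 increase_set = top_sig[d_top[top_sig] > 0],
                 decrease_set = top_sig[d_top[top_sig] < 0],
                 mean = ds$mean, sd = ds$sd),
            class = "significant_positions")
}

#' @export
print.significant_positions <- function(x, ...) {
  cat(sprintf(
    "<significant_positions> threshold %.2g SD; %d significant at top difference (%d up, %d down)\n",
    x$threshold_sd, length(x$increase_set) + length(x$decrease_set),
    length(x$increase_set), length(x$decrease_set)))
  invisible(x)
}
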