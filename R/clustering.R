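#' @title DBSCAN clustering of significant positions
#' @name clustering
#' @description Clusters the 1-based sequence positions flagged as
#'   temperature-sensitive with DBSCAN on the 1-D integer line (distance
#'   |a - b|). Default parameters are eps = 11 and MinPts = 5. Seed points
#'   are visited in ascending position order so runs are fully
#'   deterministic; a border point reachable from two clusters is assigned
#'   to the cluster discovered first.
NULL

#' DBSCAN parameters
#' @param eps neighbourhood radius in nucleotides (default 11).
#' @param min_pts minimum number of points (the point itself included)
#'   within eps for a core point (default 5).
#' @return An object of class `dbscan_params`.
#' @export
dbscan_params <- function(eps = 11L, min_pts = 5L) {
  if (length(eps) != 1L || eps != as.integer(eps) || eps < 1L)
    stop("eps must be a single integer >= 1", call. = FALSE)
  if (length(min_pts) != 1L || min_pts != as.integer(min_pts) || min_pts < 1L)
    stop("min_pts must be a single integer >= 1", call. = FALSE)
  structure(list(eps = as.integer(eps), min_pts = as.integer(min_pts)),
            class = "dbscan_params")
}

new_cluster <- function(members) {
  members <- sort(unique(as.integer(members)))
  structure(list(start = members[1L], end = members[length(members)],
                 members = members,
                 length = members[length(members)] - members[1L] + 1L,
                 density = length(members) /
                   (members[length(members)] - members[1L] + 1L)),
            class = "rna_cluster")
}

#' @export
print.rna_cluster <- function(x, ...) {
  cat(sprintf("<cluster> %d..%d (length %d, %d members, density %.3f)\n",
              x$start, x$end, x$length, length(x$members), x$density))
  invisible(x)
}

#' DBSCAN on 1-D integer positions
#'
#' Standard DBSCAN specialised to integers on a line: a position is a core
#' point when at least `min_pts` of the input positions (itself included)
#' lie within distance `eps`; clusters are the maximal density-connected
#' sets; positions in no cluster are noise. Seeds are expanded in
#' ascending order, which fixes the only order-dependent outcome of DBSCAN
#' (border points reachable from two clusters).
#'
#' @param positions integer vector of distinct 1-based positions (any
#'   order).
#' @param params a [dbscan_params()].
#' @return List of `rna_cluster` objects sorted by start position; each has
#'   `start`, `end`, `members`, `length` (= end - start + 1) and `density`
#'   (= members / length).
#' @examples
#' dbscan_1d(c(100:104, 300:310))
#' @export
dbscan_1d <- function(positions, params = dbscan_params()) {
  stopifnot(inherits(params, "dbscan_params"))
  pos <- sort(unique(as.integer(positions)))
  n <- length(pos)
  if (!n) return(list())
  # neighbourhood sizes via two-pointer sweep over the sorted positions
  lo <- findInterval(pos - params$eps - 0.5, pos) + 1L
  hi <- findInterval(pos + params$eps + 0.5, pos)
  ncount <- hi - lo + 1L
  core <- ncount >= params$min_pts
  label <- integer(n)           # 0 = unassigned/noise
  cl <- 0L
  for (s in seq_len(n)) {
    if (!core[s] || label[s] != 0L) next
    cl <- cl + 1L
    queue <- s
    label[s] <- cl
    while (length(queue)) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      if (!core[q]) next
      nb <- lo[q]:hi[q]
      for (t in nb) {
        if (label[t] == 0L) {
          label[t] <- cl
          if (core[t]) queue <- c(queue, t)
        }
      }
    }
  }
  ids <- setdiff(sort(unique(label)), 0L)
  clusters <- lapply(ids, function(id) new_cluster(pos[label == id]))
  clusters[order(vapply(clusters, `[[`, integer(1), "start"))]
}

#' Summary statistics over a cluster list
#'
#' @param clusters list of `rna_cluster` objects (as from [dbscan_1d()]).
#' @return List with `n_clusters`, `avg_density` and `avg_length`
#'   (unweighted means over clusters; `NA` when there are no clusters).
#' @export
cluster_summary <- function(clusters) {
  if (!length(clusters))
    return(list(n_clusters = 0L, avg_density = NA_real_,
                avg_length = NA_real_))
  list(n_clusters = length(clusters),
       avg_density = mean(vapply(clusters, `[[`, numeric(1), "density")),
       avg_length = mean(vapply(clusters, `[[`, numeric(1), "length")))
}

#' Cluster table
#'
#' @param clusters list of `rna_cluster` objects.
#' @return data.frame with columns `cluster_id`, `start`, `end`, `length`,
#'   `n_members`, `density`.
#' @export
cluster_table <- function(clusters) {
  data.frame(
    cluster_id = seq_along(clusters),
    start = vapply(clusters, `[[`, integer(1), "start"),
    end = vapply(clusters, `[[`, integer(1), "end"),
    length = vapply(clusters, `[[`, integer(1), "length"),
    n_members = vapply(clusters, function(cl) length(cl$members), integer(1)),
    density = vapply(clusters, `[[`, numeric(1), "density"))
}

#' Sliding-window density profile of significant positions
#'
#' A window of size 2 * eps + 1 is moved in steps of one position over the
#' sequence; for each start the percentage of window positions that are
#' significant is reported. When the sequence is shorter than the window a
#' single full-sequence window is used.
#'
#' @param positions integer vector of significant positions.
#' @param seq_length sequence length L.
#' @param eps DBSCAN radius defining the window size (default 11).
#' @return data.frame with columns `window_start` and `percent` (0--100).
#' @export
density_profile <- function(positions, seq_length, eps = 11L) {
  stopifnot(seq_length >= 1L)
  win <- 2L * as.integer(eps) + 1L
  flag <- integer(seq_length)
  pos <- unique(as.integer(positions))
  if (length(pos)) {
    if (any(pos < 1L | pos > seq_length))
      stop("positions outside 1..seq_length", call. = FALSE)
    flag[pos] <- 1L
  }
  if (seq_length < win)
    return(data.frame(window_start = 1L,
                      percent = 100 * sum(flag) / seq_length))
  cs <- c(0L, cumsum(flag))
  starts <- seq_len(seq_length - win + 1L)
  counts <- cs[starts + win] - cs[starts]
  data.frame(window_start = starts, percent = 100 * counts / win)
}
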