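#' @title Two-sequence comparison
#' @name pairwise
#' @description Compares the significant positions and clusters of two
#'   homologous, same-length sequences analysed with identical parameters.
#'   Positions significant in both sequences at a given temperature are
#'   shared; the rest are sequence-specific. A cluster is sequence-specific
#'   when its start--end span shares no position with any cluster span of
#'   the other sequence.
NULL

#' Classify significant positions as shared or sequence-specific
#'
#' @param sig_a,sig_b `significant_positions` for the two sequences,
#'   computed over the same temperature range.
#' @return List with `shared` (named list per elevated temperature),
#'   `specific_a`, `specific_b` (same structure).
#' @export
classify_positions <- function(sig_a, sig_b) {
  stopifnot(inherits(sig_a, "significant_positions"),
            inherits(sig_b, "significant_positions"))
  if (!identical(dim(sig_a$flags), dim(sig_b$flags)) ||
      !identical(names(sig_a$per_temperature), names(sig_b$per_temperature)))
    stop("the two analyses must cover the same temperatures and length",
         call. = FALSE)
  temps <- names(sig_a$per_temperature)
  shared <- specific_a <- specific_b <- setNames(vector("list", length(temps)), temps)
  for (t in temps) {
    a <- sig_a$per_temperature[[t]]
    b <- sig_b$per_temperature[[t]]
    shared[[t]] <- sort(intersect(a, b))
    specific_a[[t]] <- sort(setdiff(a, b))
    specific_b[[t]] <- sort(setdiff(b, a))
  }
  list(shared = shared, specific_a = specific_a, specific_b = specific_b)
}

span_overlaps <- function(c1, c2) {
  max(c1$start, c2$start) <= min(c1$end, c2$end)
}

#' Identify sequence-specific clusters
#'
#' A cluster of one sequence is specific when its span overlaps (shares at
#' least one sequence position with) no cluster span of the other
#' sequence.
#'
#' @param clusters_a,clusters_b cluster lists from [dbscan_1d()], computed
#'   with identical parameters.
#' @return List with `specific_a` and `specific_b`, each a list of
#'   `rna_cluster` objects.
#' @export
specific_clusters <- function(clusters_a, clusters_b) {
  is_specific <- function(cl, others) {
    !any(vapply(others, function(o) span_overlaps(cl, o), logical(1)))
  }
  list(
    specific_a = Filter(function(cl) is_specific(cl, clusters_b), clusters_a),
    specific_b = Filter(function(cl) is_specific(cl, clusters_a), clusters_b))
}

#' Perturbation-onset temperature of a position
#'
#' The lowest elevated temperature at which the position is flagged as
#' significantly changing; `NA` when it never is.
#'
#' @param sig a `significant_positions` object.
#' @param position 1-based sequence position.
#' @return Integer temperature in degrees Celsius, or `NA`.
#' @export
onset_temperature <- function(sig, position) {
  stopifnot(inherits(sig, "significant_positions"))
  if (position < 1L || position > ncol(sig$flags))
    stop("position outside the sequence", call. = FALSE)
  hit <- which(sig$flags[, position])
  if (!length(hit)) return(NA_integer_)
  as.integer(rownames(sig$flags)[hit[1L]])
}

#' Onset temperature of a cluster
#'
#' The minimum onset over the cluster's member positions.
#'
#' @param sig a `significant_positions` object.
#' @param cluster an `rna_cluster`.
#' @return Integer temperature, or `NA` when no member has an onset.
#' @export
cluster_onset <- function(sig, cluster) {
  on <- vapply(cluster$members, function(p) onset_temperature(sig, p),
               integer(1))
  on <- on[!is.na(on)]
  if (!length(on)) NA_integer_ else min(on)
}

# --- annotated comparison rendering ---------------------------------------

mark_row <- function(n, shared, specific) {
  row <- rep(".", n)
  row[shared] <- "*"
  row[specific] <- "o"
  row
}

#' Render the annotated two-sequence comparison
#'
#' Produces a plain-text block layout: a position ruler, the first
#' sequence, one mark row per elevated temperature (using that
#' temperature's own significance calls; `*` = significant in both
#' sequences, `o` = sequence-specific), a match line between the two
#' sequence blocks (`|` match, `-` mismatch/substitution), then the second
#' sequence's mark rows and residues. The HTML rendering colours the
#' residues themselves: blue for shared, orange for sequence-specific.
#'
#' @param a,b the two [rna_sequence()] objects.
#' @param sig_a,sig_b their `significant_positions`.
#' @param width positions per block in the text layout (default 60).
#' @param format `"text"` or `"html"`.
#' @return Character scalar holding the rendering.
#' @export
render_comparison <- function(a, b, sig_a, sig_b, width = 60L,
                              format = c("text", "html")) {
  format <- match.arg(format)
  validate_sequence_pair(a, b)
  cls <- classify_positions(sig_a, sig_b)
  av <- seq_chars(a); bv <- seq_chars(b)
  n <- length(av)
  temps <- names(sig_a$per_temperature)
  t1 <- as.integer(temps[1L]) - 1L  # labels below use t1 -> t
  if (format == "html")
    return(render_comparison_html(a, b, cls, av, bv, temps, t1))
  match_line <- ifelse(av == bv, "|", "-")
  out <- character(0)
  lab_w <- max(nchar(c(paste0(t1, "-", temps, " A"), "match", "pos"))) + 1L
  pad <- function(lab) formatC(lab, width = lab_w, flag = "-")
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    ruler <- rep(" ", e - s + 1L)
    for (p in s:e) if (p %% 10 == 0 || p == s) {
      digits <- strsplit(as.character(p), "")[[1]]
      at <- p - s + 1L
      if (at + length(digits) - 1L <= length(ruler))
        ruler[at:(at + length(digits) - 1L)] <- digits
    }
    out <- c(out, paste0(pad("pos"), paste(ruler, collapse = "")))
    out <- c(out, paste0(pad(if (nzchar(a$id)) a$id else "seq A"),
                         paste(av[s:e], collapse = "")))
    for (t in temps) {
      row <- mark_row(n, cls$shared[[t]], cls$specific_a[[t]])
      out <- c(out, paste0(pad(paste0(t1, "-", t, " A")),
                           paste(row[s:e], collapse = "")))
    }
    out <- c(out, paste0(pad("match"), paste(match_line[s:e], collapse = "")))
    for (t in temps) {
      row <- mark_row(n, cls$shared[[t]], cls$specific_b[[t]])
      out <- c(out, paste0(pad(paste0(t1, "-", t, " B")),
                           paste(row[s:e], collapse = "")))
    }
    out <- c(out, paste0(pad(if (nzchar(b$id)) b$id else "seq B"),
                         paste(bv[s:e], collapse = "")), "")
  }
  paste(out, collapse = "\n")
}

render_comparison_html <- function(a, b, cls, av, bv, temps, t1) {
  colour_seq <- function(chars, shared, specific) {
    spans <- chars
    spans[shared] <- sprintf("<span style=\"color:blue\">%s</span>", chars[shared])
    spans[specific] <- sprintf("<span style=\"color:orange\">%s</span>", chars[specific])
    paste(spans, collapse = "")
  }
  rows <- character(0)
  for (t in temps) {
    rows <- c(rows, sprintf(
      "<tr><td>%d-%s</td><td class=\"seq\">%s</td></tr>", t1, t,
      colour_seq(av, cls$shared[[t]], cls$specific_a[[t]])))
  }
  match_line <- paste(ifelse(av == bv, "|", "-"), collapse = "")
  rows <- c(rows, sprintf("<tr><td></td><td class=\"seq\">%s</td></tr>", match_line))
  for (t in temps) {
    rows <- c(rows, sprintf(
      "<tr><td>%d-%s</td><td class=\"seq\">%s</td></tr>", t1, t,
      colour_seq(bv, cls$shared[[t]], cls$specific_b[[t]])))
  }
  paste0("<html><head><style>td.seq{font-family:monospace;",
         "white-space:pre;}</style></head><body>\n",
         "<p>", if (nzchar(a$id)) a$id else "seq A", " (top) vs ",
         if (nzchar(b$id)) b$id else "seq B", " (bottom); blue = shared, ",
         "orange = sequence-specific</p>\n<table>\n",
         paste(rows, collapse = "\n"),
         "\n</table></body></html>\n")
}
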