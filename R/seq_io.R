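#' @title RNA sequence input, validation and substitution accounting
#' @name seq_io
#' @description Readers and validators for the one- or two-sequence input:
#'   FASTA or bare-sequence parsing, alphabet normalization (T is replaced
#'   by U, case is folded to upper), the server-style input limits
#'   (length at most 9999 nt, temperatures within 0--99 degrees C, span at
#'   most 20 degrees), and the substitution spectrum between two homologous
#'   sequences.
NULL

MAX_SEQ_LENGTH <- 9999L
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Construct a validated RNA sequence
#'
#' @param residues character scalar of residues over A, C, G, U (T and
#'   lowercase are normalized first).
#' @param id sequence identifier (FASTA header text, may be empty).
#' @param is_coding logical; treat the sequence as protein-coding when
#'   generating in-silico mutants (synonymous substitutions only).
#' @return An object of class `rna_sequence`: a list with elements `id`,
#'   `residues` and `is_coding`.
#' @examples
#' rna_sequence("acgt")$residues  # "ACGU"
#' @export
rna_sequence <- function(residues, id = "", is_coding = TRUE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[ \t\r\n]", "", residues))
  res <- gsub("T", "U", res, fixed = TRUE)
  if (nchar(res) < 1L)
    stop("sequence is empty", call. = FALSE)
  if (nchar(res) > MAX_SEQ_LENGTH)
    stop("sequence exceeds the maximal length of ", MAX_SEQ_LENGTH, " nt",
         call. = FALSE)
  bad <- setdiff(unique(strsplit(res, "")[[1]]), RNA_ALPHABET)
  if (length(bad))
    stop("illegal character(s) in sequence: ", paste(bad, collapse = ", "),
         "; allowed characters are A, C, G, U and T", call. = FALSE)
  structure(list(id = as.character(id), residues = res,
                 is_coding = isTRUE(is_coding)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s%d nt, %s\n",
              if (nzchar(x$id)) paste0(x$id, ", ") else "",
              nchar(x$residues),
              if (x$is_coding) "coding" else "non-coding"))
  cat(" ", abbreviate_seq(x$residues), "\n")
  invisible(x)
}

abbreviate_seq <- function(res, width = 60L) {
  if (nchar(res) <= width) res
  else paste0(substr(res, 1L, width - 3L), "...")
}

#' Read a single sequence from FASTA text or a bare sequence
#'
#' Accepts either one FASTA record (the header may be omitted) or a bare
#' sequence string, as pasted into a text field. Files are supported by
#' passing a path.
#'
#' @param text FASTA text, a bare sequence, or a path to a file holding one.
#' @param is_coding logical, stored on the returned sequence.
#' @return An [rna_sequence()].
#' @examples
#' read_rna_sequence(">s1\nACGT")$residues  # "ACGU"
#' @export
read_rna_sequence <- function(text, is_coding = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[\n>]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) > 1L)
    stop("input contains more than one FASTA record; provide one sequence",
         call. = FALSE)
  id <- ""
  if (length(headers) == 1L) {
    if (headers != 1L)
      stop("malformed FASTA: header is not the first line", call. = FALSE)
    id <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("sequence is empty", call. = FALSE)
  rna_sequence(paste(lines, collapse = ""), id = id, is_coding = is_coding)
}

#' Validate that two sequences can be compared
#'
#' The two-sequence analysis requires equal lengths; no alignment is
#' performed.
#'
#' @param a,b [rna_sequence()] objects.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_sequence_pair <- function(a, b) {
  stopifnot(inherits(a, "rna_sequence"), inherits(b, "rna_sequence"))
  if (nchar(a$residues) != nchar(b$residues))
    stop("the two sequences must have the same length (got ",
         nchar(a$residues), " and ", nchar(b$residues), " nt)", call. = FALSE)
  invisible(TRUE)
}

#' Construct and validate a temperature range
#'
#' Temperatures are integer degrees Celsius. The allowed window is 0--99
#' degrees C and the span t2 - t1 + 1 may be at most 20 degrees (so e.g.
#' 30--49 is accepted and 30--50 is not). The default range is 32--39.
#'
#' @param t1,t2 integer temperatures in degrees Celsius, `t1 < t2`.
#' @return An object of class `temperature_range` with elements `t1`, `t2`
#'   and `temperatures` (the integer sequence `t1:t2`).
#' @export
temperature_range <- function(t1 = 32L, t2 = 39L) {
  if (length(t1) != 1L || length(t2) != 1L ||
      t1 != as.integer(t1) || t2 != as.integer(t2))
    stop("t1 and t2 must be single integers", call. = FALSE)
  t1 <- as.integer(t1); t2 <- as.integer(t2)
  if (t1 < 0L || t2 > 99L)
    stop("temperatures must lie within 0..99 degrees C", call. = FALSE)
  if (t1 >= t2)
    stop("t1 must be strictly below t2", call. = FALSE)
  if (t2 - t1 + 1L > 20L)
    stop("temperature span t2 - t1 + 1 = ", t2 - t1 + 1L,
         " exceeds the maximum of 20 degrees C", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, temperatures = t1:t2),
            class = "temperature_range")
}

#' @export
print.temperature_range <- function(x, ...) {
  cat(sprintf("<temperature_range> %d..%d degrees C (%d temperatures)\n",
              x$t1, x$t2, length(x$temperatures)))
  invisible(x)
}

#' Substitution spectrum between two homologous sequences
#'
#' Tallies the positions at which `a` and `b` differ and the relative
#' frequency of each ordered substitution type (from-base to to-base, read
#' from `a` to `b`). The spectrum drives spectrum-matched in-silico
#' mutagenesis of non-coding sequences: if 25 percent of the natural
#' substitutions are U to C, then 25 percent of the random mutations drawn
#' from the spectrum are U to C.
#'
#' @param a,b equal-length [rna_sequence()] objects.
#' @return An object of class `substitution_spectrum`: list with `count`
#'   (the Hamming distance), `positions` (1-based mismatch positions),
#'   `type_frequencies` (named numeric, names like `"U>C"`, summing to 1
#'   when `count > 0`).
#' @export
substitution_spectrum <- function(a, b) {
  validate_sequence_pair(a, b)
  av <- strsplit(a$residues, "")[[1]]
  bv <- strsplit(b$residues, "")[[1]]
  pos <- which(av != bv)
  if (!length(pos)) {
    freq <- numeric(0)
  } else {
    types <- paste0(av[pos], ">", bv[pos])
    tab <- table(types)
    freq <- as.numeric(tab) / length(pos)
    names(freq) <- names(tab)
  }
  structure(list(count = length(pos), positions = pos,
                 type_frequencies = freq),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("<substitution_spectrum> %d substitution(s)\n", x$count))
  if (x$count > 0) {
    for (nm in names(x$type_frequencies))
      cat(sprintf("  %s : %.3f\n", nm, x$type_frequencies[[nm]]))
  }
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

seq_codes <- function(seq) {
  match(seq_chars(seq), RNA_ALPHABET) - 1L
}
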