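#' @title In-silico mutant data sets
#' @name mutagen
#' @description Generates the random mutant data set used by the
#'   cluster-specificity test: derivatives of the first sequence carrying
#'   exactly N substitutions each. Coding sequences receive synonymous
#'   single-base codon changes only (standard genetic code, frame 1);
#'   non-coding sequences receive substitutions at uniformly random
#'   positions whose from-to types mimic the substitution spectrum
#'   observed between the two input sequences.
NULL

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

rna_genetic_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      names(gc) <- gsub("T", "U", names(gc), fixed = TRUE)
      code <<- gc
    }
    code
  }
})

#' Translate an RNA sequence (standard code, frame 1)
#'
#' @param seq an [rna_sequence()] whose length is divisible by 3.
#' @return Character scalar of amino acids (stop = `*`).
#' @export
translate_rna <- function(seq) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- nchar(seq$residues)
  if (n %% 3L != 0L)
    stop("sequence length must be divisible by 3 for translation",
         call. = FALSE)
  codons <- substring(seq$residues, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(rna_genetic_code()[codons], collapse = "")
}

# all single-base codon changes that leave the encoded amino acid intact
synonymous_options <- function(seq) {
  gc <- rna_genetic_code()
  n <- nchar(seq$residues)
  codons <- substring(seq$residues, seq(1L, n, 3L), seq(3L, n, 3L))
  out <- list()
  for (ci in seq_along(codons)) {
    cod <- strsplit(codons[ci], "")[[1]]
    aa <- gc[[codons[ci]]]
    for (off in 1:3) for (b in setdiff(RNA_ALPHABET, cod[off])) {
      alt <- cod
      alt[off] <- b
      if (identical(gc[[paste(alt, collapse = "")]], aa))
        out[[length(out) + 1L]] <- list(codon = ci,
                                        site = (ci - 1L) * 3L + off,
                                        from = cod[off], to = b)
    }
  }
  out
}

new_mutant_set <- function(parent, n_subs, regime, sequences, seed) {
  structure(list(parent_id = parent$id, n_substitutions = as.integer(n_subs),
                 regime = regime, sequences = sequences,
                 seed = as.integer(seed)),
            class = "mutant_set")
}

#' @export
print.mutant_set <- function(x, ...) {
  cat(sprintf("<mutant_set> %d %s mutant(s), %d substitution(s) each (seed %d)\n",
              length(x$sequences), x$regime, x$n_substitutions, x$seed))
  invisible(x)
}

#' Synonymous mutant data set for a coding sequence
#'
#' Each mutant carries exactly `n_subs` single-base substitutions, each of
#' which leaves the encoded amino acid unchanged (standard genetic code,
#' frame 1). Substitutions within one mutant target distinct codons, so
#' they are jointly synonymous and the Hamming distance to the parent is
#' exactly `n_subs`. Mutants are sampled independently; duplicates are
#' permitted. The result is fully determined by `seed`.
#'
#' @param parent a coding [rna_sequence()] whose length is divisible by 3.
#' @param n_subs number of substitutions per mutant (N).
#' @param n_mutants number of mutants to generate (default 100).
#' @param seed RNG seed.
#' @return A `mutant_set`.
#' @export
synonymous_mutants <- function(parent, n_subs, n_mutants = 100L, seed = 1L) {
  stopifnot(inherits(parent, "rna_sequence"))
  n <- nchar(parent$residues)
  if (n %% 3L != 0L)
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  if (n_subs < 1L)
    stop("n_subs must be at least 1 (identical sequences leave nothing to test)",
         call. = FALSE)
  opts <- synonymous_options(parent)
  codons_avail <- unique(vapply(opts, `[[`, integer(1), "codon"))
  if (length(codons_avail) < n_subs)
    stop("only ", length(codons_avail), " codon(s) admit a synonymous ",
         "single-base change; cannot place ", n_subs,
         " substitutions per mutant", call. = FALSE)
  parent_chars <- seq_chars(parent)
  with_seed(seed, {
    sequences <- vector("list", n_mutants)
    for (m in seq_len(n_mutants)) {
      chars <- parent_chars
      used_codons <- integer(0)
      for (s in seq_len(n_subs)) {
        eligible <- Filter(function(o) !(o$codon %in% used_codons), opts)
        pick <- eligible[[sample.int(length(eligible), 1L)]]
        chars[pick$site] <- pick$to
        used_codons <- c(used_codons, pick$codon)
      }
      sequences[[m]] <- rna_sequence(paste(chars, collapse = ""),
                                     id = sprintf("%s_mut%04d",
                                                  if (nzchar(parent$id)) parent$id else "parent", m),
                                     is_coding = TRUE)
    }
    new_mutant_set(parent, n_subs, "coding", sequences, seed)
  })
}

#' Spectrum-matched mutant data set for a non-coding sequence
#'
#' Each mutant receives exactly `spectrum$count` substitutions at distinct
#' uniformly random positions; every substitution's from-to type is drawn
#' from the spectrum's type frequencies and applied at a position whose
#' current base matches the drawn from-base (types without an eligible
#' position are rejection-resampled). The result is fully determined by
#' `seed`.
#'
#' @param parent an [rna_sequence()].
#' @param spectrum a [substitution_spectrum()] with `count >= 1`.
#' @param n_mutants number of mutants (default 100).
#' @param seed RNG seed.
#' @return A `mutant_set`.
#' @export
spectrum_mutants <- function(parent, spectrum, n_mutants = 100L, seed = 1L) {
  stopifnot(inherits(parent, "rna_sequence"),
            inherits(spectrum, "substitution_spectrum"))
  if (spectrum$count < 1L)
    stop("the substitution spectrum is empty; the sequences are identical",
         call. = FALSE)
  types <- names(spectrum$type_frequencies)
  freqs <- as.numeric(spectrum$type_frequencies)
  from_base <- substr(types, 1L, 1L)
  to_base <- substr(types, 3L, 3L)
  parent_chars <- seq_chars(parent)
  max_attempts <- 100L * spectrum$count
  with_seed(seed, {
    sequences <- vector("list", n_mutants)
    for (m in seq_len(n_mutants)) {
      chars <- parent_chars
      mutated <- integer(0)
      attempts <- 0L
      while (length(mutated) < spectrum$count) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("substitution spectrum infeasible on this sequence: no ",
               "eligible position for the drawn substitution types",
               call. = FALSE)
        ty <- sample.int(length(types), 1L, prob = freqs)
        eligible <- setdiff(which(parent_chars == from_base[ty]), mutated)
        if (!length(eligible)) next
        pos <- eligible[sample.int(length(eligible), 1L)]
        chars[pos] <- to_base[ty]
        mutated <- c(mutated, pos)
      }
      sequences[[m]] <- rna_sequence(paste(chars, collapse = ""),
                                     id = sprintf("%s_mut%04d",
                                                  if (nzchar(parent$id)) parent$id else "parent", m),
                                     is_coding = FALSE)
    }
    new_mutant_set(parent, spectrum$count, "noncoding", sequences, seed)
  })
}

#' Write a mutant set as multi-record FASTA
#'
#' @param mutants a `mutant_set`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_mutants_fasta <- function(mutants, path) {
  stopifnot(inherits(mutants, "mutant_set"))
  set <- Biostrings::RNAStringSet(
    vapply(mutants$sequences, `[[`, character(1), "residues"))
  names(set) <- vapply(mutants$sequences, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
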