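# Independent brute-force oracles and small generators shared by the tests.

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  rna_sequence(paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

hamming_dist <- function(x, y) {
  a <- strsplit(if (inherits(x, "rna_sequence")) x$residues else x, "")[[1]]
  b <- strsplit(if (inherits(y, "rna_sequence")) y$residues else y, "")[[1]]
  sum(a != b)
}

# Brute-force DBSCAN on integers: explicit neighbourhood enumeration,
# connected components over core points, border points attached to the
# first-discovered (lowest minimal-core) component.
brute_dbscan <- function(positions, eps, min_pts) {
  pos <- sort(unique(as.integer(positions)))
  n <- length(pos)
  if (!n) return(list(clusters = list(), noise = integer(0)))
  nbr <- lapply(seq_len(n), function(i) which(abs(pos - pos[i]) <= eps))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || comp[i] != 0L) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        reach <- intersect(nbr[[f]], which(core & comp == 0L))
        comp[reach] <- cid
        nxt <- c(nxt, reach)
      }
      frontier <- nxt
    }
  }
  # border points: first component (ascending id) with a core neighbour
  for (i in seq_len(n)) {
    if (core[i] || comp[i] != 0L) next
    cand <- comp[intersect(nbr[[i]], which(core))]
    if (length(cand)) comp[i] <- min(cand)
  }
  ids <- setdiff(sort(unique(comp)), 0L)
  list(clusters = lapply(ids, function(id) pos[comp == id]),
       noise = pos[comp == 0L])
}

# one-sided binomial tails by direct pmf summation
binom_upper_tail <- function(k, n, p) {
  if (k > n) return(0)
  x <- k:n
  sum(choose(n, x) * p^x * (1 - p)^(n - x))
}
binom_lower_tail <- function(k, n, p) {
  x <- 0:k
  sum(choose(n, x) * p^x * (1 - p)^(n - x))
}

# fold provider returning a constant profile regardless of temperature
constant_backend <- function(value) {
  function(seq, temperature_celsius, opts)
    rep(value, nchar(seq$residues))
}

# provider with an explicit per-temperature lookup: profiles is a named
# list "t" -> numeric vector
table_backend <- function(profiles) {
  function(seq, temperature_celsius, opts) {
    p <- profiles[[as.character(temperature_celsius)]]
    stopifnot(!is.null(p), length(p) == nchar(seq$residues))
    p
  }
}

# random coding parent built from codons that admit synonymous single-base
# changes (avoids AUG/UGG-style dead codons)
random_coding_parent <- function(n_codons) {
  synable <- c("UUA", "CUG", "AUC", "GUU", "UCA", "CCG", "ACU", "GCC",
               "UAU", "CAC", "AAU", "GAA", "UGC", "CGG", "AGA", "GGU")
  rna_sequence(paste(sample(synable, n_codons, replace = TRUE),
                     collapse = ""), id = "parent", is_coding = TRUE)
}
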