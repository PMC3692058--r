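#' @title Equilibrium pairing-probability providers
#' @name fold_engine
#' @description Per-nucleotide paired-state probabilities p(i) at a given
#'   temperature come from a pluggable backend. Two backends ship with the
#'   package: `"vienna"` invokes the RNAfold program of the ViennaRNA
#'   package (partition-function mode, reading the base-pair probability
#'   dot plot), and `"reference"` is a built-in simplified McCaskill
#'   engine over a per-pair enthalpy/entropy energy model, exactly
#'   checkable against exhaustive structure enumeration. Additional
#'   providers (e.g. deterministic synthetic profiles for testing) can be
#'   registered with [register_fold_backend()].
NULL

# Gas constant, kcal / (mol K)
GAS_CONSTANT <- 0.0019872

# Per-pair-type enthalpy (kcal/mol) and entropy (kcal/mol/K) of the
# reference engine's energy model: Delta G(pair, T) = dH - T * dS, T in
# kelvin. Constants are ordered so that G-C pairs are far more stable than
# A-U, and G-U wobble pairs weaker still; the A-U melting midpoint
# (dH/dS = 309 K) sits inside the physiological range so that A,U-rich
# helices genuinely melt across the default 32--39 degree scan. The A-U
# enthalpy is larger than a single-pair calorimetric value on purpose: the
# model has no stacking cooperativity, so a steeper per-pair transition
# stands in for the cooperative melting of a helix.
PAIR_ENERGIES <- list(
  AU = c(dH = -13.6, dS = -0.0440),
  GC = c(dH = -12.0, dS = -0.0260),
  GU = c(dH = -10.0, dS = -0.0360)
)

MIN_HAIRPIN_LOOP <- 3L

#' Folding options
#'
#' @param no_gu forbid G-U (wobble) pairs entirely.
#' @param no_close_gu forbid G-U pairs at helix ends. For the `"vienna"`
#'   backend this maps to RNAfold's `--noCloseGU`; the reference engine
#'   approximates the rule by requiring G-U pairs to stack on the pair
#'   immediately inside them, while the enumeration oracle applies the
#'   exact either-side stacking rule.
#' @return An object of class `fold_options`.
#' @export
fold_options <- function(no_gu = FALSE, no_close_gu = FALSE) {
  structure(list(no_gu = isTRUE(no_gu), no_close_gu = isTRUE(no_close_gu)),
            class = "fold_options")
}

pair_type <- function(a, b) {
  key <- paste0(a, b)
  switch(key,
         AU = , UA = "AU",
         GC = , CG = "GC",
         GU = , UG = "GU",
         NA_character_)
}

#' Boltzmann pair-weight matrix of the reference energy model
#'
#' @param temperature_celsius integer temperature in degrees Celsius.
#' @param opts [fold_options()].
#' @return 4 x 4 numeric matrix over (A, C, G, U) with
#'   `exp(-(dH - T dS) / (R T))` for allowed pair types and 0 elsewhere.
#' @keywords internal
pair_weights <- function(temperature_celsius, opts = fold_options()) {
  tk <- temperature_celsius + 273.15
  w <- matrix(0, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  for (a in RNA_ALPHABET) for (b in RNA_ALPHABET) {
    ty <- pair_type(a, b)
    if (!is.na(ty) && !(opts$no_gu && ty == "GU")) {
      e <- PAIR_ENERGIES[[ty]]
      dg <- e[["dH"]] - tk * e[["dS"]]
      w[a, b] <- exp(-dg / (GAS_CONSTANT * tk))
    }
  }
  w
}

check_temperature <- function(temperature_celsius) {
  if (length(temperature_celsius) != 1L ||
      temperature_celsius != as.integer(temperature_celsius))
    stop("temperature must be a single integer (degrees Celsius)",
         call. = FALSE)
  t <- as.integer(temperature_celsius)
  if (t < 0L || t > 99L)
    stop("temperature must lie within 0..99 degrees C", call. = FALSE)
  t
}

#' Base-pair probability matrix from the built-in reference engine
#'
#' Runs McCaskill-style inside/outside recursions over all pseudoknot-free
#' secondary structures with a minimum hairpin loop of 3 unpaired bases and
#' a per-pair Boltzmann weight `exp(-(dH - T dS)/(R T))`. No stacking or
#' loop terms are included; the model is deliberately minimal so the result
#' is exactly checkable against [enumerate_structures()].
#'
#' @param seq an [rna_sequence()].
#' @param temperature_celsius integer temperature, 0--99 degrees C.
#' @param opts [fold_options()].
#' @return A symmetric n x n matrix P with `P[i, j]` the equilibrium
#'   probability that nucleotides i and j are paired; zero on and near the
#'   diagonal (|j - i| < 4). Attribute `log_z` holds the log partition
#'   function.
#' @export
reference_pair_matrix <- function(seq, temperature_celsius,
                                  opts = fold_options()) {
  stopifnot(inherits(seq, "rna_sequence"))
  t <- check_temperature(temperature_celsius)
  res <- mcc_engine(seq_codes(seq), pair_weights(t, opts),
                    opts$no_close_gu, TRUE)
  structure(res$P, log_z = res$log_z)
}

reference_paired_vector <- function(seq, temperature_celsius,
                                    opts = fold_options()) {
  t <- check_temperature(temperature_celsius)
  res <- mcc_engine(seq_codes(seq), pair_weights(t, opts),
                    opts$no_close_gu, FALSE)
  res$p
}

# --- backend registry ------------------------------------------------------

.fold_backends <- new.env(parent = emptyenv())

#' Register a pairing-probability backend
#'
#' A backend is a function `function(seq, temperature_celsius, opts)`
#' returning a numeric vector of per-nucleotide paired-state probabilities
#' in `[0, 1]`, one per residue. Registration makes the backend available
#' by name everywhere a `backend` argument is accepted, which is how tests
#' inject fully deterministic synthetic profiles.
#'
#' @param name backend name.
#' @param fun provider function, or `NULL` to unregister.
#' @export
register_fold_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(fun)) {
    if (exists(name, envir = .fold_backends)) rm(list = name, envir = .fold_backends)
  } else {
    stopifnot(is.function(fun))
    assign(name, fun, envir = .fold_backends)
  }
  invisible(name)
}

#' List registered backends
#' @return Character vector of backend names.
#' @export
fold_backends <- function() sort(ls(envir = .fold_backends))

get_fold_backend <- function(name) {
  if (is.function(name)) return(name)
  if (!exists(name, envir = .fold_backends))
    stop("unknown fold backend '", name, "'; registered: ",
         paste(fold_backends(), collapse = ", "), call. = FALSE)
  get(name, envir = .fold_backends)
}

#' Per-nucleotide paired-state probabilities
#'
#' Computes p(i), the equilibrium probability that nucleotide i is paired
#' with any partner (the row sum of the base-pair probability matrix), at
#' one temperature through the selected backend.
#'
#' @param seq an [rna_sequence()].
#' @param temperature_celsius integer temperature, 0--99 degrees C.
#' @param opts [fold_options()].
#' @param backend backend name (see [fold_backends()]) or a provider
#'   function.
#' @return Numeric vector of length `nchar(seq$residues)` with values in
#'   `[0, 1]`.
#' @examples
#' s <- rna_sequence("GGGGAAAACCCC")
#' p <- pairing_probabilities(s, 37)
#' @export
pairing_probabilities <- function(seq, temperature_celsius,
                                  opts = fold_options(),
                                  backend = "reference") {
  stopifnot(inherits(seq, "rna_sequence"))
  t <- check_temperature(temperature_celsius)
  fun <- get_fold_backend(backend)
  p <- fun(seq, t, opts)
  n <- nchar(seq$residues)
  if (!is.numeric(p) || length(p) != n)
    stop("backend returned ", length(p), " probabilities for a ", n,
         "-nt sequence", call. = FALSE)
  if (any(!is.finite(p)) || any(p < -1e-9) || any(p > 1 + 1e-9))
    stop("backend returned probabilities outside [0, 1]", call. = FALSE)
  pmin(pmax(p, 0), 1)
}

# --- ViennaRNA adapter -----------------------------------------------------

#' Locate the RNAfold executable
#' @return Path to RNAfold, or `""` when not found.
#' @keywords internal
find_rnafold <- function() Sys.which("RNAfold")

vienna_backend <- function(seq, temperature_celsius, opts) {
  exe <- find_rnafold()
  if (!nzchar(exe))
    stop("the 'vienna' backend requires the RNAfold executable on PATH",
         call. = FALSE)
  dir <- tempfile("rnafold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  owd <- setwd(dir)
  on.exit(setwd(owd), add = TRUE)
  args <- c("-p", "--noPS", paste0("--temp=", temperature_celsius))
  if (opts$no_gu) args <- c(args, "--noGU")
  if (opts$no_close_gu) args <- c(args, "--noCloseGU")
  out <- suppressWarnings(
    system2(exe, args, stdout = TRUE, stderr = TRUE, input = seq$residues))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("RNAfold failed (exit ", status, "): ",
         paste(utils::tail(out, 3), collapse = " / "), call. = FALSE)
  dp <- list.files(dir, pattern = "dot\\.ps$|_dp\\.ps$", full.names = TRUE)
  if (!length(dp))
    stop("RNAfold produced no dot-plot file", call. = FALSE)
  parse_dotplot(readLines(dp[[1]], warn = FALSE), nchar(seq$residues))
}

# Extract p(i) = sum_j P(i, j) from RNAfold's PostScript dot plot; 'ubox'
# entries hold sqrt(P(i, j)).
parse_dotplot <- function(lines, n) {
  ub <- grep("ubox$", lines, value = TRUE)
  ub <- ub[grepl("^[0-9]+ [0-9]+ [0-9.eE+-]+ ubox$", ub)]
  p <- numeric(n)
  if (length(ub)) {
    f <- read.table(text = ub, col.names = c("i", "j", "v", "tag"))
    prob <- f$v^2
    for (r in seq_len(nrow(f))) {
      p[f$i[r]] <- p[f$i[r]] + prob[r]
      p[f$j[r]] <- p[f$j[r]] + prob[r]
    }
  }
  pmin(pmax(p, 0), 1)
}

#' Version string of the available ViennaRNA backend
#' @return Character scalar such as `"RNAfold 2.7.2"`, or `NA` when the
#'   executable is absent.
#' @export
vienna_version <- function() {
  exe <- find_rnafold()
  if (!nzchar(exe)) return(NA_character_)
  out <- suppressWarnings(system2(exe, "--version", stdout = TRUE, stderr = TRUE))
  trimws(out[[1]])
}

# --- exhaustive enumeration oracle ----------------------------------------

#' Enumerate all secondary structures of a short sequence
#'
#' Lists every pseudoknot-free set of non-crossing legal pairs with a
#' minimum hairpin loop of 3 unpaired bases, including the empty structure.
#' Intended as a brute-force oracle for the reference engine; refuses
#' sequences longer than `max_len`.
#'
#' Under `no_close_gu` the exact rule is applied: a G-U pair is kept only
#' when it stacks on an adjacent pair on either side (the pair immediately
#' inside or immediately outside it is also present).
#'
#' @param seq an [rna_sequence()].
#' @param opts [fold_options()].
#' @param max_len combinatorial safety bound (default 25).
#' @return List of integer matrices with columns `i`, `j` (one row per
#'   pair; the empty structure is a 0-row matrix).
#' @export
enumerate_structures <- function(seq, opts = fold_options(), max_len = 25L) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- nchar(seq$residues)
  if (n > max_len)
    stop("sequence too long for exhaustive enumeration (", n, " > ",
         max_len, ")", call. = FALSE)
  ch <- seq_chars(seq)
  pairable <- function(i, j) {
    ty <- pair_type(ch[i], ch[j])
    !is.na(ty) && !(opts$no_gu && ty == "GU")
  }
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j)                       # i unpaired
    for (k in seq_len(j - i + 1L) + i - 1L) {
      if (k >= i + MIN_HAIRPIN_LOOP + 1L && pairable(i, k)) {
        left <- enum(i + 1L, k - 1L)
        right <- enum(k + 1L, j)
        for (s1 in left) for (s2 in right)
          out <- c(out, list(rbind(matrix(c(i, k), 1, 2), s1, s2)))
      }
    }
    memo[[key]] <- out
    out
  }
  structs <- enum(1L, n)
  if (opts$no_close_gu && !opts$no_gu)
    structs <- Filter(function(s) gu_pairs_stacked(s, ch), structs)
  lapply(structs, function(s) {
    colnames(s) <- c("i", "j")
    if (nrow(s) > 1L) s <- s[order(s[, 1L]), , drop = FALSE]
    s
  })
}

# exact no-close-GU rule: every G-U pair must have an adjacent pair
# (i+1, j-1) or (i-1, j+1) in the same structure
gu_pairs_stacked <- function(s, ch) {
  if (!nrow(s)) return(TRUE)
  key <- paste(s[, 1L], s[, 2L])
  for (r in seq_len(nrow(s))) {
    i <- s[r, 1L]; j <- s[r, 2L]
    if (identical(pair_type(ch[i], ch[j]), "GU")) {
      inner <- paste(i + 1L, j - 1L) %in% key
      outer <- paste(i - 1L, j + 1L) %in% key
      if (!inner && !outer) return(FALSE)
    }
  }
  TRUE
}

#' Boltzmann-averaged pair matrix from exhaustive enumeration
#'
#' Computes the same quantity as [reference_pair_matrix()] by brute force:
#' each enumerated structure is weighted by the product of its pair
#' Boltzmann factors, and pair frequencies are averaged over the ensemble.
#'
#' @inheritParams enumerate_structures
#' @param temperature_celsius integer temperature, 0--99 degrees C.
#' @return Symmetric n x n probability matrix.
#' @export
enumerated_pair_matrix <- function(seq, temperature_celsius,
                                   opts = fold_options(), max_len = 25L) {
  t <- check_temperature(temperature_celsius)
  structs <- enumerate_structures(seq, opts, max_len)
  w <- pair_weights(t, opts)
  ch <- seq_chars(seq)
  n <- length(ch)
  P <- matrix(0, n, n)
  z <- 0
  for (s in structs) {
    wt <- 1
    if (nrow(s))
      for (r in seq_len(nrow(s))) wt <- wt * w[ch[s[r, 1L]], ch[s[r, 2L]]]
    z <- z + wt
    if (nrow(s))
      for (r in seq_len(nrow(s))) {
        P[s[r, 1L], s[r, 2L]] <- P[s[r, 1L], s[r, 2L]] + wt
        P[s[r, 2L], s[r, 1L]] <- P[s[r, 2L], s[r, 1L]] + wt
      }
  }
  P / z
}
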