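Package: rnatherm
Title: Temperature-Induced Perturbation Analysis of RNA Secondary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects temperature-sensitive regions of RNA secondary structure
    from equilibrium base-pairing probabilities computed across a temperature
    range. Positions whose paired-state probability changes by more than a
    user-set number of standard deviations are clustered along the sequence
    with DBSCAN. Two homologous same-length RNAs can be compared to find
    sequence-specific temperature-sensitive clusters, and an in-silico
    mutagenesis procedure (synonymous-only for coding RNAs, substitution-
    spectrum-matched for non-coding RNAs) combined with one-sided exact
    binomial tests assesses whether those clusters are attributable to the
    particular nucleotide substitutions separating the sequences. Pairing
    probabilities come either from the ViennaRNA RNAfold program or from a
    built-in simplified McCaskill partition-function engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA RNAfold (optional, for the 'vienna' backend)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
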