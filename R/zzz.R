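.onLoad <- function(libname, pkgname) {
  register_fold_backend("reference", function(seq, temperature_celsius, opts)
    reference_paired_vector(seq, temperature_celsius, opts))
  register_fold_backend("vienna", vienna_backend)
  invisible()
}
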