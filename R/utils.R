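# Seed derivation: participant i of a cohort seeded with `seed` gets a
# deterministic child seed via a splittable counter scheme, so cohorts can be
# extended without reshuffling earlier participants. Kept within 32-bit
# integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
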