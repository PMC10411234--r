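# All randomness in the package flows through this wrapper: a single named
# generator (Mersenne-Twister + inversion), seeded explicitly per call, with
# the caller's RNG state restored afterwards. No function mutates global
# RNG state as a side effect.
local_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}
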