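# run expr under a fixed seed (restoring global RNG state), or in the
# current RNG state when seed is NULL — all package randomness funnels
# through this
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# round to the 0-4 clinical score scale in 0.5 steps
quantize_cs <- function(x) {
  pmin(4, pmax(0, round(x * 2) / 2))
}
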