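# Internal helpers: classed conditions and reproducible RNG scoping.

chem_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("chemgsea_", class), "chemgsea_error"), ...)
}

# Derive a child seed from a parent seed and a fixed integer offset.
# Linear-congruential step keeps the result a valid 32-bit integer; products
# stay below 2^53 so the double arithmetic is exact.
child_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) * 48271 + abs(as.numeric(offset))) %% 2147483629
  as.integer(s)
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_rng <- function(seed, code) {
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x != round(x) || x < min) {
    chem_abort(sprintf("`%s` must be a single integer >= %d", name, min), "domain")
  }
  as.integer(x)
}
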