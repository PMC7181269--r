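# Internal helpers shared across modules.

# Derive a child seed from a parent seed and a stream index. Constants are
# small enough that all arithmetic stays exact in doubles (< 2^53) for any
# parent seed below 2^31.
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((abs(seed) * 69069 + index * 30011 + 1013) %% 2147483647)
}

# Round half away from zero (display convention for percentage tables;
# base::round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- rlang::`%||%`
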