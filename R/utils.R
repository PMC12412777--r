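# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Largest divisor of `n` that is <= `k`; used by the group-normalization
# grouping rule so small test-scale widths always normalize cleanly.
largest_divisor_leq <- function(n, k) {
  for (g in seq(min(n, k), 1L)) if (n %% g == 0L) return(as.integer(g))
  1L
}

is_binary <- function(x) all(x == 0 | x == 1)

# Stable per-component seed derivation from one master seed. Arithmetic is
# exact in doubles (all intermediates < 2^53) and the result fits a 32-bit
# integer, so derived runs are reproducible across platforms.
derive_seed <- function(master, component) {
  stopifnot(is.character(component), length(component) == 1L)
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(component)) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

same_dim <- function(a, b) identical(dim(a), dim(b))

vol_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) abort("expected a 3D volume")
  d
}

# Named stop with a consistent class so callers/tests can target validation
# failures specifically.
fail_validation <- function(msg) abort(msg, class = "adaptdose_validation_error")
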