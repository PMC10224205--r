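## Internal helpers: seeded evaluation without touching global RNG state
## outside the call, and derived per-stage seeds.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a master seed and an index; kept inside the 32-bit
# signed integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 99991 * as.double(index)) %% 2147483629) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

# Validate that a probability vector sums to one.
check_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stopf("configuration error: %s probabilities must be non-negative and sum to 1", what)
  }
  invisible(p)
}
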