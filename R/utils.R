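# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All seeded operations in the package go
# through this so that (config, seed) fully determines outputs.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream-specific child seed from a base seed. Arithmetic in
# doubles (exact below 2^53), folded back into 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 1009 + abs(as.numeric(stream)) * 7919) %%
               2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg) stop(msg, call. = FALSE)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
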