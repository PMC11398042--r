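# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream indices, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed)
  for (i in idx) s <- (s * 69069 + i) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
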