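# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps all simulator randomness
# insulated from user code.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit signed integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
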