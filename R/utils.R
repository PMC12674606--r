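# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one user-facing seed into per-component streams.
# Offsets keep streams distinct; the modulus keeps results inside R's 32-bit
# integer range for any small input seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 10007 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}
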