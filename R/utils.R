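# Internal helpers shared across modules.

# Evaluate expr with a temporarily-seeded RNG, restoring global RNG state.
# Every stochastic operation in the package routes randomness through this so
# that a seed argument fully determines the result without clobbering the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct sub-seed for a named stage from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483587) + 1L
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
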