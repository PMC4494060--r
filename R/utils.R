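## Internal helpers shared across modules.

#' Evaluate an expression with a private RNG stream
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so generators are pure functions of (parameters,
#' seed) and never perturb test or session randomness.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
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

## Round half away from zero at `digits` decimals (base round() is
## round-half-even, which would misreport e.g. 0.25 -> 0.2).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Positive modulo: result always in [0, m).
pmod <- function(x, m) ((x %% m) + m) %% m

## Circular (great-circle style) distance between two positions on a circle
## of length L: min(d, L - d), in [0, L/2].
circ_dist <- function(a, b, L) {
  d <- pmod(a - b, L)
  pmin(d, L - d)
}

stop_arch <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
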