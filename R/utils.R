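## Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so seeded internals (Monte-Carlo
#' calibration, bootstrap) do not perturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @noRd
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## x*log(y) with the 0*log(0) = 0 convention (Poisson log-likelihood terms)
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

## Derive a reproducible 32-bit sub-seed from a parent seed and a counter,
## so parallel-safe per-molecule / per-window streams stay decoupled.
subSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 1103515245) %% 2147483647L)
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
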