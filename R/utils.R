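# Internal numeric helpers shared across modules.

softplus <- function(x) {
  # log(1 + exp(x)) computed without overflow for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  y + log(-expm1(-y))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not perturb user-level random streams.
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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

# argmax with deterministic tie-break toward the lowest index
which_max_first <- function(x) which(x == max(x))[1L]

`%||%` <- function(a, b) if (is.null(a)) b else a
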