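#' @keywords internal
#' @useDynLib cmiCollab, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Canonical base ordering used everywhere: rows of the embedding table,
# composition vectors, skip-gram count matrices.
RNA_BASES <- c("A", "C", "G", "U")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded library calls never
#' disturb the caller's RNG stream. All stochastic entry points in the
#' package route their randomness through this helper, which is what makes
#' them pure functions of their `seed` argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) {
  ifelse(x >= 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.2) {
  ifelse(x >= 0, 1, slope)
}

#' Clamp probabilities away from 0 and 1
#' @keywords internal
clamp_prob <- function(p, eps = 1e-7) {
  pmin(pmax(p, eps), 1 - eps)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
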