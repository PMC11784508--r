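#' Numerically safe logarithm
#'
#' All logarithms in the engine go through this function. Identity likelihood
#' mappings contain exact zeros, so a small constant is added before taking
#' the log to keep every term finite.
#'
#' @param x numeric vector, matrix or array.
#' @param eps stabilising constant added before the log.
#' @return `log(x + eps)`, same shape as `x`.
#' @export
ln_safe <- function(x, eps = 1e-16) {
  log(x + eps)
}

#' Softmax
#'
#' @param x numeric vector of real-valued scores.
#' @return a probability vector proportional to `exp(x)`.
#' @export
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# column-wise softmax for a matrix of log-state vectors
softmax_cols <- function(m) {
  n <- nrow(m)
  mx <- m[max.col(t(m), ties.method = "first") + n * (seq_len(ncol(m)) - 1L)]
  e <- exp(m - rep(mx, each = n))
  e / rep(colSums(e), each = n)
}

#' Derive a reproducible sub-stream seed
#'
#' Cohort simulations give every agent (or every seed replicate) its own RNG
#' stream derived from the master seed and an index, so that any single agent
#' can be re-run in isolation. The derivation is a fixed affine map kept
#' within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param master master seed (integer).
#' @param index non-negative stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) + 104729 * as.numeric(index)) %% 2147483587)
}

# stop() with a consistent prefix, no call
abort <- function(...) stop(..., call. = FALSE)

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
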