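#' Validate a categorical probability vector
#'
#' A categorical vector has non-negative entries that sum to one. These
#' vectors carry state priors (D), observations (o) and posteriors (s)
#' throughout the engine.
#'
#' @param x numeric vector.
#' @param tol tolerance on the unit-sum check.
#' @return `x`, unchanged, if valid; otherwise an error.
#' @export
categorical <- function(x, tol = 1e-10) {
  if (!is.numeric(x) || length(x) < 1L) abort("categorical vector must be numeric")
  if (any(!is.finite(x)) || any(x < 0)) abort("categorical vector entries must be finite and >= 0")
  if (abs(sum(x) - 1) > tol) abort("categorical vector must sum to 1 (got ", format(sum(x), digits = 12), ")")
  x
}

#' Dirichlet concentration counts
#'
#' Tags a vector, matrix or array of strictly positive counts with a
#' `learnable` flag. Learnable blocks are incremented by experience
#' (see [update_a()], [update_d()]); locked blocks are left untouched and
#' contribute no novelty during policy evaluation.
#'
#' @param x numeric counts, all strictly positive.
#' @param learnable logical flag.
#' @return `x` with attribute `learnable`.
#' @export
dirichlet_counts <- function(x, learnable = TRUE) {
  if (!is.numeric(x)) abort("counts must be numeric")
  if (any(!is.finite(x)) || any(x <= 0)) abort("Dirichlet counts must be strictly positive")
  attr(x, "learnable") <- isTRUE(learnable)
  x
}

#' Is a count block learnable?
#' @param x a counts object.
#' @return logical.
#' @export
is_learnable <- function(x) isTRUE(attr(x, "learnable"))

#' Normalise Dirichlet counts to a categorical distribution
#'
#' Divides each column by its sum (the expectation of the Dirichlet
#' distribution the counts parameterise). Vectors are treated as a single
#' column; matrices column-wise; 3-d arrays slice by slice along the first
#' margin pair.
#'
#' @param counts numeric vector, matrix or array of non-negative counts.
#' @return object of the same shape whose columns sum to 1.
#' @export
normalize_counts <- function(counts) {
  learn <- attr(counts, "learnable")
  out <- if (is.null(dim(counts))) {
    s <- sum(counts)
    if (s <= 0) abort("zero-sum column in counts: degenerate Dirichlet block")
    counts / s
  } else if (length(dim(counts)) == 2L) {
    cs <- colSums(counts)
    if (any(cs <= 0)) abort("zero-sum column in counts: degenerate Dirichlet block")
    sweep(counts, 2L, cs, "/")
  } else {
    apply(counts, seq_along(dim(counts))[-1L], function(col) {
      s <- sum(col)
      if (s <= 0) abort("zero-sum column in counts: degenerate Dirichlet block")
      col / s
    })
  }
  attr(out, "learnable") <- learn
  out
}

#' Optimism-conditioned biased likelihood for binary good/bad outcomes
#'
#' Builds the 2 x 2 x 2 likelihood table used by the belief-updating task:
#' outcomes (good news, bad news) by belief states (good outcome, bad
#' outcome) by optimism states (optimistic, pessimistic). The optimistic
#' slice is
#' \deqn{\begin{bmatrix} a_{good} & 1-a_{bad} \\ 1-a_{good} & a_{bad} \end{bmatrix}}
#' and the pessimistic slice swaps the roles of the two precision
#' parameters, mirroring the bias.
#'
#' @param a_good precision on the good-outcome state column, in (0,1).
#' @param a_bad precision on the bad-outcome state column, in (0,1).
#' @return a 2 x 2 x 2 array with dimnames
#'   `news x belief x optimism`; every column is a categorical vector.
#' @export
make_biased_likelihood <- function(a_good, a_bad) {
  for (p in c(a_good = a_good, a_bad = a_bad)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
      abort("precision parameters must lie strictly inside (0, 1)")
  }
  optimistic  <- matrix(c(a_good, 1 - a_good, 1 - a_bad, a_bad), 2L, 2L)
  pessimistic <- matrix(c(a_bad, 1 - a_bad, 1 - a_good, a_good), 2L, 2L)
  out <- array(c(optimistic, pessimistic), dim = c(2L, 2L, 2L),
               dimnames = list(news = c("good", "bad"),
                               belief = c("good", "bad"),
                               optimism = c("optimistic", "pessimistic")))
  out
}

#' Lock a likelihood mapping by inflating its concentration
#'
#' Scaling Dirichlet counts leaves the normalised mapping unchanged but
#' makes unit-count experience negligible: a mapping multiplied by 1000
#' shifts by less than 1e-3 per added observation. When the scale factor is
#' large (>= 100) the `learnable` flag is cleared, so the block neither
#' accumulates counts nor generates a novelty drive.
#'
#' @param counts Dirichlet counts (vector, matrix or array).
#' @param factor scale factor, >= 1.
#' @return scaled counts; `learnable` cleared when `factor >= 100`.
#' @export
lock_precision <- function(counts, factor = 1000) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1)
    abort("lock factor must be a single number >= 1")
  out <- counts * factor
  attr(out, "learnable") <- if (factor >= 100) FALSE else isTRUE(attr(counts, "learnable"))
  out
}
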