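#' Dirichlet likelihood learning
#'
#' Implements the trial-wise concentration-parameter update
#' \deqn{a_{trial+1} = a_{trial} + \sum_t o_t \otimes s_t}
#' where `o_t` is the observation (one-hot or soft) and `s_t` the hidden
#' state posterior averaged over policies. Each timestep adds exactly one
#' unit of count mass. Locked (non-learnable) blocks are returned
#' unchanged with a warning.
#'
#' @param counts Dirichlet counts (`outcomes x joint-states`).
#' @param observations observation matrix (`outcomes x T`) or a single
#'   vector; columns need not be one-hot.
#' @param state_posteriors posterior matrix (`joint-states x T`) or a
#'   single vector (the Bayesian model average over policies).
#' @return updated counts, same shape and `learnable` flag.
#' @export
update_a <- function(counts, observations, state_posteriors) {
  if (!is_learnable(counts)) {
    warning("update_a called on a locked block; counts unchanged", call. = FALSE)
    return(counts)
  }
  o <- if (is.null(dim(observations))) matrix(observations, ncol = 1L) else as.matrix(observations)
  s <- if (is.null(dim(state_posteriors))) matrix(state_posteriors, ncol = 1L) else as.matrix(state_posteriors)
  if (ncol(o) != ncol(s)) abort("observations and posteriors disagree on timestep count")
  if (nrow(o) != nrow(counts) || nrow(s) != ncol(counts))
    abort("update shape mismatch: counts are ", nrow(counts), " x ", ncol(counts))
  out <- counts + tcrossprod(o, s)
  attr(out, "learnable") <- TRUE
  out
}

#' Dirichlet initial-state learning
#'
#' \deqn{d_{trial+1} = d_{trial} + s_{\tau=1}}: the first-timestep state
#' posterior is added to the prior's concentration counts, accumulating
#' one unit of mass per trial.
#'
#' @param counts Dirichlet counts over one factor's levels.
#' @param first_state_posterior categorical vector, the \eqn{\tau = 1}
#'   posterior marginal for that factor.
#' @return updated counts.
#' @export
update_d <- function(counts, first_state_posterior) {
  if (!is_learnable(counts)) {
    warning("update_d called on a locked block; counts unchanged", call. = FALSE)
    return(counts)
  }
  if (length(first_state_posterior) != length(counts))
    abort("posterior length must match d counts")
  out <- counts + as.numeric(first_state_posterior)
  attr(out, "learnable") <- TRUE
  out
}

#' Optimism level of an agent
#'
#' The optimism factor has two states, optimistic then pessimistic. The
#' optimism level is the first entry of the normalised Dirichlet counts:
#' counts `[0.8, 0.2]` (or any rescaling) give level 0.8.
#'
#' @param d Dirichlet counts of the two-state optimism factor.
#' @return numeric in `[0, 1]`.
#' @export
optimism_level <- function(d) {
  if (length(d) != 2L) abort("the optimism factor must have exactly two states")
  as.numeric(normalize_counts(as.numeric(d)))[1L]
}
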