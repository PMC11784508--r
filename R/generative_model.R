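#' Construct a categorical POMDP generative model
#'
#' The generative model is the agent's joint distribution over hidden
#' states and observations: per-factor state priors `D` (with Dirichlet
#' counts `d`), per-modality likelihood mappings `A` (with counts `a`),
#' per-factor transition mappings `B`, log-domain outcome preferences `C`,
#' and a set of allowed policies. Hidden state factors are combined into a
#' joint state space with the first factor varying fastest, so a modality
#' conditioned on several factors stores its likelihood as an
#' `outcomes x joint-states` table (a 3-d `outcomes x factor1 x factor2`
#' array is accepted and flattened in that order).
#'
#' @param factors named list; each element a list with `levels` (character
#'   vector of state names) and `d` (positive Dirichlet counts, see
#'   [dirichlet_counts()]).
#' @param modalities named list; each element a list with `outcomes`
#'   (character vector) and `a` (counts, `outcomes x joint-states`).
#' @param transitions named list (one entry per factor) of lists of square
#'   transition matrices, one per action, columns summing to 1. Missing
#'   entries default to a single identity action.
#' @param preferences named list of real-valued preference weights per
#'   modality (log domain; softmax-normalised before use). Missing
#'   modalities default to zero weights (no preference).
#' @param policies list of integer vectors, one action index per factor.
#'   Defaults to a single all-identity policy.
#' @param horizon number of timesteps per trial.
#' @param policy_precision inverse temperature applied to negated expected
#'   free energy when forming the policy posterior.
#' @return an object of class `gen_model`.
#' @export
generative_model <- function(factors, modalities, transitions = NULL,
                             preferences = NULL, policies = NULL,
                             horizon = 1L, policy_precision = 1) {
  if (is.null(names(factors)) || any(names(factors) == ""))
    abort("factors must be a named list")
  if (is.null(names(modalities)) || any(names(modalities) == ""))
    abort("modalities must be a named list")

  factors <- lapply(factors, function(f) {
    f$d <- dirichlet_counts(as.numeric(f$d),
                            learnable = isTRUE(attr(f$d, "learnable")) || isTRUE(f$learnable))
    if (length(f$d) != length(f$levels)) abort("factor d length must match its levels")
    f
  })
  nf <- vapply(factors, function(f) length(f$levels), integer(1))
  n_joint <- prod(nf)

  modalities <- lapply(modalities, function(m) {
    a <- m$a
    learn <- isTRUE(attr(a, "learnable")) || isTRUE(m$learnable)
    if (!is.null(dim(a)) && length(dim(a)) > 2L) a <- matrix(a, nrow = dim(a)[1L])
    if (is.null(dim(a))) a <- matrix(a, ncol = 1L)
    if (nrow(a) != length(m$outcomes)) abort("modality 'a' rows must match its outcomes")
    if (ncol(a) != n_joint) abort("modality 'a' must have one column per joint state (", n_joint, ")")
    m$a <- dirichlet_counts(a, learnable = learn)
    m
  })

  if (is.null(transitions)) transitions <- list()
  for (fn in names(factors)) {
    if (is.null(transitions[[fn]]))
      transitions[[fn]] <- list(diag(length(factors[[fn]]$levels)))
    for (B in transitions[[fn]]) {
      if (!is.matrix(B) || any(dim(B) != length(factors[[fn]]$levels)))
        abort("transition matrix for factor '", fn, "' has the wrong shape")
      if (any(abs(colSums(B) - 1) > 1e-10))
        abort("transition matrix columns for factor '", fn, "' must sum to 1")
    }
  }

  if (is.null(preferences)) preferences <- list()
  for (mn in names(modalities)) {
    if (is.null(preferences[[mn]]))
      preferences[[mn]] <- rep(0, length(modalities[[mn]]$outcomes))
    if (length(preferences[[mn]]) != length(modalities[[mn]]$outcomes) ||
        any(!is.finite(preferences[[mn]])))
      abort("preference weights for modality '", mn, "' must be finite, one per outcome")
  }

  if (is.null(policies)) policies <- list(rep(1L, length(factors)))
  policies <- lapply(policies, function(p) {
    p <- as.integer(p)
    if (length(p) != length(factors)) abort("each policy needs one action per factor")
    for (i in seq_along(p)) {
      if (p[i] < 1L || p[i] > length(transitions[[names(factors)[i]]]))
        abort("policy indexes a missing transition slice for factor '", names(factors)[i], "'")
    }
    p
  })

  structure(list(factors = factors, modalities = modalities,
                 transitions = transitions, preferences = preferences,
                 policies = policies, horizon = as.integer(horizon),
                 policy_precision = policy_precision),
            class = "gen_model")
}

#' @export
print.gen_model <- function(x, ...) {
  cat("<gen_model>", length(x$factors), "state factor(s),",
      length(x$modalities), "modality(ies),",
      length(x$policies), "policy(ies), horizon", x$horizon, "\n")
  for (fn in names(x$factors)) {
    f <- x$factors[[fn]]
    cat("  factor", fn, "(", paste(f$levels, collapse = "/"), ")",
        if (is_learnable(f$d)) "[d learnable]" else "", "\n")
  }
  for (mn in names(x$modalities)) {
    m <- x$modalities[[mn]]
    cat("  modality", mn, "(", paste(m$outcomes, collapse = "/"), ")",
        if (is_learnable(m$a)) "[a learnable]" else "", "\n")
  }
  invisible(x)
}

#' Number of joint hidden states of a model
#' @param model a `gen_model`.
#' @return integer.
#' @export
n_joint_states <- function(model) {
  prod(vapply(model$factors, function(f) length(f$levels), integer(1)))
}

#' Joint initial-state prior
#'
#' Outer product of the per-factor normalised `d` counts, first factor
#' varying fastest.
#'
#' @param model a `gen_model`.
#' @return categorical vector over joint states.
#' @export
joint_prior <- function(model) {
  ds <- lapply(model$factors, function(f) as.numeric(normalize_counts(f$d)))
  Reduce(function(hi, lo) as.numeric(kronecker(hi, lo)), rev(ds))
}

#' Expected likelihood mapping of a modality
#'
#' @param model a `gen_model`.
#' @param modality modality name.
#' @return `outcomes x joint-states` matrix with unit-sum columns.
#' @export
likelihood <- function(model, modality) {
  m <- model$modalities[[modality]]
  if (is.null(m)) abort("unknown modality '", modality, "'")
  normalize_counts(m$a)
}

#' Joint transition matrix under a policy
#'
#' @param model a `gen_model`.
#' @param policy policy index into `model$policies`.
#' @return `joint x joint` transition matrix (columns sum to 1).
#' @export
joint_transition <- function(model, policy = 1L) {
  acts <- model$policies[[policy]]
  Bs <- Map(function(fn, a) model$transitions[[fn]][[a]], names(model$factors), acts)
  Reduce(function(hi, lo) kronecker(hi, lo), rev(Bs))
}

#' Marginalise a joint-state distribution onto one factor
#'
#' @param model a `gen_model`.
#' @param s numeric vector over joint states (or matrix with joint states
#'   in rows, e.g. a posterior trajectory).
#' @param factor factor name.
#' @return marginal distribution over that factor's levels (vector, or
#'   matrix if `s` was a matrix).
#' @export
factor_marginal <- function(model, s, factor) {
  nf <- vapply(model$factors, function(f) length(f$levels), integer(1))
  idx <- match(factor, names(model$factors))
  if (is.na(idx)) abort("unknown factor '", factor, "'")
  level_of <- as.vector(slice.index(array(0L, dim = nf), idx))
  agg <- function(v) as.numeric(rowsum(v, level_of))
  if (is.matrix(s)) {
    out <- apply(s, 2L, agg)
    rownames(out) <- model$factors[[idx]]$levels
    out
  } else {
    stats::setNames(agg(s), model$factors[[idx]]$levels)
  }
}

#' Construct a generative process (the environment)
#'
#' The generative process shares the structure of a generative model --
#' factors, transition mappings, likelihood mappings -- but carries the
#' environment's true parameters, and has no preferences, policies or
#' learning. It supplies the initial state, state transitions under the
#' agent's actions, and sampled outcomes.
#'
#' @param factors named list as in [generative_model()] (the `d` entries
#'   are the true initial-state distributions).
#' @param likelihoods named list of `outcomes x joint-states` probability
#'   matrices (the true mappings, columns summing to 1).
#' @param transitions as in [generative_model()].
#' @param policies as in [generative_model()]; the process must accept the
#'   same action indices as the paired model.
#' @return an object of class `gen_process`.
#' @export
generative_process <- function(factors, likelihoods, transitions = NULL,
                               policies = NULL) {
  skeleton <- generative_model(factors = factors,
                               modalities = lapply(likelihoods, function(L) {
                                 list(outcomes = rownames(L) %||% paste0("o", seq_len(nrow(L))),
                                      a = dirichlet_counts(pmax(L, 1e-12), learnable = FALSE))
                               }),
                               transitions = transitions, policies = policies)
  for (mn in names(likelihoods)) {
    if (any(abs(colSums(likelihoods[[mn]]) - 1) > 1e-10))
      abort("process likelihood '", mn, "' columns must sum to 1")
  }
  structure(list(skeleton = skeleton, likelihoods = likelihoods),
            class = "gen_process")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample the initial joint state of a generative process
#' @param process a `gen_process`.
#' @return integer joint-state index.
#' @export
process_initial_state <- function(process) {
  sample.int(n_joint_states(process$skeleton), 1L, prob = joint_prior(process$skeleton))
}

#' Advance the generative process one step under an action
#' @param process a `gen_process`.
#' @param state current joint-state index.
#' @param policy action (policy index into the skeleton's policies).
#' @return next joint-state index (sampled from the transition column).
#' @export
process_step <- function(process, state, policy) {
  B <- joint_transition(process$skeleton, policy)
  sample.int(nrow(B), 1L, prob = B[, state])
}

#' Sample observations from a generative process
#' @param process a `gen_process`.
#' @param state joint-state index.
#' @return named list of one-hot observation vectors, one per modality.
#' @export
process_observe <- function(process, state) {
  lapply(process$likelihoods, function(L) {
    o <- numeric(nrow(L))
    o[sample.int(nrow(L), 1L, prob = L[, state])] <- 1
    names(o) <- rownames(L)
    o
  })
}
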