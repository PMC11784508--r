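#' Novelty weight matrix W
#'
#' \deqn{W := \tfrac{1}{2}\,(a^{\odot(-1)} - a_{sums}^{\odot(-1)})}
#' where `a` holds the Dirichlet concentration counts of a likelihood
#' mapping and `a_sums` repeats each column's sum. W weights the novelty
#' (expected information gain) term of expected free energy: cells backed
#' by few counts have large W and attract observation; as counts grow W
#' shrinks to zero.
#'
#' @param counts strictly positive Dirichlet counts (vector or matrix).
#' @return matrix (or vector) of the same shape, entries >= 0.
#' @export
novelty_weight <- function(counts) {
  if (any(!is.finite(counts)) || any(counts <= 0))
    abort("novelty weights require strictly positive counts")
  if (is.null(dim(counts))) {
    0.5 * (1 / counts - 1 / sum(counts))
  } else {
    sums <- matrix(colSums(counts), nrow(counts), ncol(counts), byrow = TRUE)
    0.5 * (1 / counts - 1 / sums)
  }
}

#' Expected free energy of a policy
#'
#' Scores a policy by
#' \deqn{G_\pi = \sum_\tau \big(
#'   \underbrace{A s_{\pi,\tau} \cdot (\ln A s_{\pi,\tau} - \ln C)}_{risk}
#'   - \underbrace{\mathrm{diag}(A^T \ln A) \cdot s_{\pi,\tau}}_{-ambiguity}
#'   - \underbrace{A s_{\pi,\tau} \cdot W s_{\pi,\tau}}_{novelty} \big)}
#' summed over modalities. The returned `ambiguity` component is the
#' expected outcome entropy \eqn{-\mathrm{diag}(A^T \ln A) \cdot s \ge 0},
#' so `G = sum(risk + ambiguity - novelty)`. Preferences `C` are
#' softmax-normalised before the logarithm, which makes the risk term a
#' proper divergence (non-negative) and leaves policy posteriors invariant
#' to constant shifts of the preference weights. Novelty is evaluated only
#' for modalities whose counts are learnable; locked mappings generate no
#' epistemic drive.
#'
#' @param model a [generative_model()].
#' @param belief a `belief_state` from [infer_states()] (beliefs computed
#'   for this same policy).
#' @param policy policy index (recorded in the result).
#' @param timesteps which timesteps to score; defaults to all.
#' @return object of class `policy_eval`: list with `G` (scalar), and
#'   per-timestep `risk`, `ambiguity`, `novelty`, plus `predicted`
#'   (per-modality predicted outcome distributions `A s`).
#' @export
expected_free_energy <- function(model, belief, policy = belief$policy,
                                 timesteps = NULL) {
  s <- if (inherits(belief, "belief_state")) belief$s else as.matrix(belief)
  if (is.null(timesteps)) timesteps <- seq_len(ncol(s))
  nt <- length(timesteps)
  risk <- ambiguity <- novelty <- numeric(nt)
  predicted <- list()

  for (mn in names(model$modalities)) {
    A <- likelihood(model, mn)
    Cw <- model$preferences[[mn]]
    if (is.null(Cw)) abort("missing preference vector for modality '", mn, "'")
    lnC <- log(softmax(Cw))
    lnA <- ln_safe(A)
    amb_state <- -colSums(A * lnA)            # outcome entropy per joint state
    learn <- is_learnable(model$modalities[[mn]]$a)
    W <- if (learn) novelty_weight(model$modalities[[mn]]$a) else NULL
    pred_m <- matrix(NA_real_, nrow(A), nt)
    for (k in seq_len(nt)) {
      st <- s[, timesteps[k]]
      o_pred <- as.numeric(A %*% st)
      pred_m[, k] <- o_pred
      risk[k] <- risk[k] + sum(o_pred * (ln_safe(o_pred) - lnC))
      ambiguity[k] <- ambiguity[k] + sum(amb_state * st)
      if (learn)
        novelty[k] <- novelty[k] + sum(o_pred * as.numeric(W %*% st))
    }
    rownames(pred_m) <- model$modalities[[mn]]$outcomes
    predicted[[mn]] <- pred_m
  }

  structure(list(G = sum(risk + ambiguity - novelty),
                 risk = risk, ambiguity = ambiguity, novelty = novelty,
                 predicted = predicted, policy = policy,
                 timesteps = timesteps),
            class = "policy_eval")
}

#' @export
print.policy_eval <- function(x, ...) {
  cat("<policy_eval> policy", x$policy, " G =", format(x$G, digits = 6),
      "(risk", format(sum(x$risk), digits = 4),
      "+ ambiguity", format(sum(x$ambiguity), digits = 4),
      "- novelty", format(sum(x$novelty), digits = 4), ")\n")
  invisible(x)
}

#' Posterior over policies
#'
#' \eqn{\pi = \sigma(-\gamma G)}: a softmax of negated expected free
#' energies, so lower G means higher probability. The precision
#' \eqn{\gamma} sharpens or flattens the posterior.
#'
#' @param evaluations list of `policy_eval` objects, or a numeric vector of
#'   G values.
#' @param precision inverse temperature \eqn{\gamma} (default 1).
#' @return categorical vector of policy probabilities.
#' @export
policy_posterior <- function(evaluations, precision = 1) {
  G <- if (is.numeric(evaluations)) evaluations
       else vapply(evaluations, function(e) e$G, numeric(1))
  if (length(G) < 1L) abort("at least one policy evaluation is required")
  softmax(-precision * G)
}

#' Select an action from a policy posterior
#'
#' @param posterior categorical vector of policy probabilities.
#' @param mode `"sample"` draws from the posterior (the default, matching
#'   stochastic choice behaviour); `"argmax"` picks the most probable
#'   policy deterministically, breaking ties at the lowest index.
#' @return integer policy/action index.
#' @export
select_action <- function(posterior, mode = c("sample", "argmax")) {
  mode <- match.arg(mode)
  categorical(posterior, tol = 1e-8)
  if (mode == "argmax") which.max(posterior)
  else sample.int(length(posterior), 1L, prob = posterior)
}
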