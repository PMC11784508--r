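# Independent oracle implementations used to pin down the engine's
# arithmetic. These are deliberately written as naive index-by-index loops,
# separate from the package's vectorised code paths.

# exact posterior by direct Bayes rule: p(s|o) ~ D * prod_m A_m^T o_m
oracle_bayes_posterior <- function(A_list, D, obs_list) {
  lik <- rep(1, length(D))
  for (m in seq_along(A_list)) {
    A <- A_list[[m]]
    o <- obs_list[[m]]
    for (j in seq_along(D)) {
      pj <- 0
      for (i in seq_len(nrow(A))) pj <- pj + A[i, j] * o[i]
      lik[j] <- lik[j] * pj
    }
  }
  post <- D * lik
  post / sum(post)
}

# W := 1/2 (1/a - 1/colsums(a)), element by element
oracle_W <- function(a) {
  W <- a * 0
  for (j in seq_len(ncol(a))) {
    cs <- sum(a[, j])
    for (i in seq_len(nrow(a))) W[i, j] <- 0.5 * (1 / a[i, j] - 1 / cs)
  }
  W
}

# per-timestep expected free energy terms for a single modality
# (risk with softmax-normalised C; ambiguity as expected entropy;
#  novelty o . W s); returns list(risk, ambiguity, novelty)
oracle_G_terms <- function(A, s, Cw, a_counts = NULL) {
  lc <- Cw - log(sum(exp(Cw)))
  o_pred <- numeric(nrow(A))
  for (i in seq_len(nrow(A)))
    for (j in seq_along(s)) o_pred[i] <- o_pred[i] + A[i, j] * s[j]
  risk <- 0
  for (i in seq_along(o_pred))
    risk <- risk + o_pred[i] * (log(o_pred[i] + 1e-16) - lc[i])
  amb <- 0
  for (j in seq_along(s)) {
    hj <- 0
    for (i in seq_len(nrow(A))) hj <- hj - A[i, j] * log(A[i, j] + 1e-16)
    amb <- amb + hj * s[j]
  }
  nov <- 0
  if (!is.null(a_counts)) {
    W <- oracle_W(a_counts)
    for (i in seq_len(nrow(A)))
      for (j in seq_along(s))
        nov <- nov + o_pred[i] * W[i, j] * s[j]
  }
  list(risk = risk, ambiguity = amb, novelty = nov)
}

# marginal free energy for a single-factor trajectory by direct substitution:
# F_tau = s_tau . (ln s_tau - avg(messages) - ln A^T o_tau)
oracle_F <- function(A, B, D, s_mat, obs_mat) {
  Tn <- ncol(s_mat)
  Bdag <- t(B)
  for (j in seq_len(ncol(Bdag))) {
    cs <- sum(Bdag[, j])
    Bdag[, j] <- if (cs > 0) Bdag[, j] / cs else 1 / nrow(Bdag)
  }
  out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    fwd <- if (t == 1L) log(D + 1e-16) else log(B %*% s_mat[, t - 1L] + 1e-16)
    msg <- if (t < Tn) 0.5 * (fwd + log(Bdag %*% s_mat[, t + 1L] + 1e-16)) else fwd
    lev <- log(t(A) %*% obs_mat[, t] + 1e-16)
    out[t] <- sum(s_mat[, t] * (log(s_mat[, t] + 1e-16) - msg - lev))
  }
  out
}

# random small single-factor model for property tests
random_small_model <- function(n_states = sample(2:4, 1), n_out = NULL,
                               learnable = FALSE) {
  if (is.null(n_out)) n_out <- n_states
  A <- matrix(stats::runif(n_out * n_states, 0.05, 1), n_out, n_states)
  A <- sweep(A, 2L, colSums(A), "/")
  D <- stats::runif(n_states, 0.05, 1)
  D <- D / sum(D)
  model <- generative_model(
    factors = list(state = list(levels = paste0("s", seq_len(n_states)),
                                d = dirichlet_counts(D))),
    modalities = list(obs = list(outcomes = paste0("o", seq_len(n_out)),
                                 a = dirichlet_counts(A * 4, learnable = learnable))))
  list(model = model, A = A, D = D)
}

onehot <- function(i, n) { o <- numeric(n); o[i] <- 1; o }
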