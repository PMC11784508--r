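REWARD_OUTCOMES <- c("large_win", "small_win", "null", "small_loss", "large_loss")
REWARD_PAYOFFS <- c(large_win = 4, small_win = 1, null = 0,
                    small_loss = -1, large_loss = -4)

#' Configuration for the modified two-armed bandit task
#'
#' Three locations (start, left arm, right arm), five reward outcomes with
#' fixed dollar payoffs (+4/-4 on the large-stakes left arm, +1/-1 on the
#' small-stakes right arm, 0 for staying), and three one-step policies
#' (stay, left, right). The agent's reward likelihood is conditioned on
#' the optimism factor: under the optimistic state wins are believed to
#' occur with probability `q_optimistic` on either arm, under the
#' pessimistic state with `q_pessimistic`. The environment's true
#' contingencies are `p_large_win` and `p_small_win`. Defaults are the
#' package's calibrated task configuration (see the methods vignette and
#' `inst/extdata/bandit-calibrated.yaml`).
#'
#' @param optimism_level optimism level in `[0, 1]` (from experiment 1).
#' @param n_trials trials per agent (default 60).
#' @param p_large_win true win probability of the left (large-stakes) arm.
#' @param p_small_win true win probability of the right (small-stakes) arm.
#' @param q_optimistic believed win probability under the optimistic state.
#' @param q_pessimistic believed win probability under the pessimistic state.
#' @param preferences named log-domain preference weights over the five
#'   reward outcomes, ordered large win > small win > null (fixed at 0) >
#'   small loss > large loss.
#' @param initial_mass concentration mass per column of the learnable
#'   reward counts; small values let early outcomes move beliefs quickly.
#' @param support_floor probability floor for reward outcomes an arm
#'   cannot produce (keeps every Dirichlet count positive).
#' @param policy_precision inverse temperature on negated expected free
#'   energy for action selection.
#' @param action_mode `"sample"` (default) or `"argmax"`.
#' @param seed seed for the agent's environment and choices.
#' @return list of class `bandit_config`.
#' @export
bandit_config <- function(optimism_level = 0.5, n_trials = 60L,
                          p_large_win = 0.6, p_small_win = 0.25,
                          q_optimistic = 0.8, q_pessimistic = 0.05,
                          preferences = c(large_win = 3, small_win = 1.5,
                                          null = 0, small_loss = -1.5,
                                          large_loss = -3),
                          initial_mass = 1, support_floor = 0.0025,
                          policy_precision = 4, action_mode = "sample",
                          seed = 1L) {
  for (p in c(optimism_level, p_large_win, p_small_win, q_optimistic, q_pessimistic))
    if (!is_prob(p)) abort("probabilities and the optimism level must lie in [0, 1]")
  if (n_trials < 1L) abort("n_trials must be >= 1")
  preferences <- preferences[REWARD_OUTCOMES]
  if (any(is.na(preferences))) abort("preferences must name all five reward outcomes")
  if (!(preferences["large_win"] > preferences["small_win"] &&
        preferences["small_win"] > preferences["null"] &&
        preferences["null"] > preferences["small_loss"] &&
        preferences["small_loss"] > preferences["large_loss"]))
    abort("preferences must be ordered large_win > small_win > null > small_loss > large_loss")
  if (preferences["null"] != 0) abort("the null outcome carries no preference (weight 0)")
  structure(list(optimism_level = optimism_level, n_trials = as.integer(n_trials),
                 p_large_win = p_large_win, p_small_win = p_small_win,
                 q_optimistic = q_optimistic, q_pessimistic = q_pessimistic,
                 preferences = preferences, initial_mass = initial_mass,
                 support_floor = support_floor,
                 policy_precision = policy_precision,
                 action_mode = action_mode, seed = as.integer(seed)),
            class = "bandit_config")
}

# reward probability column for one location under believed/true win prob q
reward_column <- function(location, q, floor = 0) {
  p <- stats::setNames(rep(floor, 5L), REWARD_OUTCOMES)
  if (location == "start") p["null"] <- 1
  else if (location == "left") { p["large_win"] <- q; p["large_loss"] <- 1 - q }
  else { p["small_win"] <- q; p["small_loss"] <- 1 - q }
  p / sum(p)
}

#' Build the bandit generative model and generative process
#'
#' The model has a location factor (known start position, identity
#' location likelihood, locked) and the optimism factor (precise prior at
#' the configured level, no learning). The reward modality is learnable,
#' with initial counts biased by the optimism-conditioned win beliefs; the
#' process carries the true arm contingencies, identical across optimism
#' states. Policies are one-step: stay, go left, go right.
#'
#' @param config a [bandit_config()].
#' @return list with elements `model` (a `gen_model`) and `process`
#'   (a `gen_process`).
#' @export
build_bandit_model <- function(config) {
  locs <- c("start", "left", "right")
  eps <- 1e-9
  loc_factor <- list(levels = locs,
                     d = dirichlet_counts(c(1 - 2 * eps, eps, eps), learnable = FALSE))
  opt_factor <- list(levels = c("optimistic", "pessimistic"),
                     d = dirichlet_counts(
                       pmin(pmax(c(config$optimism_level,
                                   1 - config$optimism_level), 1e-6), 1 - 1e-6),
                       learnable = FALSE))

  move_to <- function(j) { B <- matrix(0, 3L, 3L); B[j, ] <- 1; B }
  loc_trans <- list(diag(3L), move_to(2L), move_to(3L))

  A_loc <- cbind(diag(3L), diag(3L)) + 1e-6      # identity per optimism slice
  rownames(A_loc) <- locs

  a_reward <- cbind(
    vapply(locs, reward_column, numeric(5L), q = config$q_optimistic,
           floor = config$support_floor),
    vapply(locs, reward_column, numeric(5L), q = config$q_pessimistic,
           floor = config$support_floor)) * config$initial_mass
  rownames(a_reward) <- REWARD_OUTCOMES

  model <- generative_model(
    factors = list(location = loc_factor, optimism = opt_factor),
    modalities = list(
      location = list(outcomes = locs,
                      a = lock_precision(dirichlet_counts(A_loc), 1000)),
      reward = list(outcomes = REWARD_OUTCOMES,
                    a = dirichlet_counts(a_reward, learnable = TRUE))),
    transitions = list(location = loc_trans),
    preferences = list(location = rep(0, 3L),
                       reward = as.numeric(config$preferences)),
    policies = list(c(1L, 1L), c(2L, 1L), c(3L, 1L)),
    horizon = 2L, policy_precision = config$policy_precision)

  A_loc_true <- cbind(diag(3L), diag(3L)); rownames(A_loc_true) <- locs
  # true contingencies: per location, identical across optimism states
  true_q <- function(loc) switch(loc, start = NA_real_,
                                 left = config$p_large_win,
                                 right = config$p_small_win)
  A_rew_true <- vapply(locs, function(l) reward_column(l, true_q(l), floor = 0),
                       numeric(5L))
  A_rew_true <- cbind(A_rew_true, A_rew_true)
  rownames(A_rew_true) <- REWARD_OUTCOMES

  process <- generative_process(
    factors = list(location = loc_factor, optimism = opt_factor),
    likelihoods = list(location = A_loc_true, reward = A_rew_true),
    transitions = list(location = loc_trans),
    policies = list(c(1L, 1L), c(2L, 1L), c(3L, 1L)))

  list(model = model, process = process)
}

#' Run one agent on the bandit task
#'
#' Each trial is a two-timestep episode: the agent observes itself at the
#' start with a null reward, evaluates the expected free energy of the
#' three one-step policies (risk + ambiguity - novelty, with novelty
#' active on the learnable reward counts), selects an action from the
#' policy posterior, observes the sampled outcome, and updates the reward
#' counts from the full-trial posterior. Reward learning persists across
#' the 60 trials.
#'
#' @param config a [bandit_config()].
#' @return list of class `bandit_trajectory`: `trials` (data.frame with
#'   per-trial action, action probabilities, outcome, payoff, cumulative
#'   winnings), `total_winnings`, `stay_count`, `reward_counts` (final
#'   learned counts), `config`.
#' @export
run_bandit <- function(config) {
  set.seed(config$seed)
  mp <- build_bandit_model(config)
  model <- mp$model
  process <- mp$process
  actions <- c("stay", "left", "right")

  rows <- vector("list", config$n_trials)
  cumulative <- 0
  for (tr in seq_len(config$n_trials)) {
    state1 <- 1L                       # start position, known
    obs1 <- process_observe(process, state1)
    beliefs <- lapply(1:3, function(p)
      infer_states(model, list(obs1, NULL), policy = p))
    evals <- lapply(1:3, function(p)
      expected_free_energy(model, beliefs[[p]], policy = p, timesteps = 2L))
    post <- policy_posterior(evals, model$policy_precision)
    act <- select_action(post, config$action_mode)

    state2 <- process_step(process, state1, act)
    obs2 <- process_observe(process, state2)
    full <- infer_states(model, list(obs1, obs2), policy = act)
    model$modalities$reward$a <- update_a(
      model$modalities$reward$a,
      cbind(obs1$reward, obs2$reward), full$s)

    outcome <- REWARD_OUTCOMES[which.max(obs2$reward)]
    payoff <- REWARD_PAYOFFS[[outcome]]
    cumulative <- cumulative + payoff
    rows[[tr]] <- data.frame(trial = tr, action = actions[act],
                             p_stay = post[1L], p_left = post[2L],
                             p_right = post[3L], outcome = outcome,
                             payoff = payoff, cumulative = cumulative)
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, total_winnings = cumulative,
                 stay_count = sum(trials$action == "stay"),
                 reward_counts = model$modalities$reward$a,
                 config = config),
            class = "bandit_trajectory")
}

#' @export
print.bandit_trajectory <- function(x, ...) {
  cat("<bandit_trajectory> optimism", x$config$optimism_level, ":",
      nrow(x$trials), "trials, total winnings $", x$total_winnings,
      ",", x$stay_count, "stay actions\n")
  invisible(x)
}

#' Sweep optimism levels on the bandit task
#'
#' Runs `n_seeds` independent agents at every optimism level and
#' summarises engagement and performance.
#'
#' @param levels optimism levels (default 0.1 to 0.9).
#' @param config a [bandit_config()] used as the template; its `seed` is
#'   the master seed from which per-agent seeds are derived.
#' @param n_seeds agents per level (default 25).
#' @return data.frame with one row per level: `level`, `median_winnings`,
#'   `mean_winnings`, `q25`, `q75`, `stay_prop` (proportion of stay
#'   actions), `left_prop`, `right_prop`, `modal_stay_count` (most common
#'   per-agent stay count across seeds).
#' @export
run_optimism_sweep <- function(levels = seq(0.1, 0.9, by = 0.1),
                               config = bandit_config(), n_seeds = 25L) {
  if (any(levels < 0 | levels > 1)) abort("levels must lie in [0, 1]")
  rows <- lapply(seq_along(levels), function(li) {
    winnings <- stays <- lefts <- rights <- numeric(n_seeds)
    for (k in seq_len(n_seeds)) {
      cfg <- config
      cfg$optimism_level <- levels[li]
      cfg$seed <- derive_seed(config$seed, k)   # same agent seeds per level
      res <- run_bandit(cfg)
      winnings[k] <- res$total_winnings
      stays[k] <- res$stay_count
      lefts[k] <- sum(res$trials$action == "left")
      rights[k] <- sum(res$trials$action == "right")
    }
    n_tr <- config$n_trials
    data.frame(level = levels[li],
               median_winnings = stats::median(winnings),
               mean_winnings = mean(winnings),
               q25 = stats::quantile(winnings, 0.25, names = FALSE),
               q75 = stats::quantile(winnings, 0.75, names = FALSE),
               stay_prop = mean(stays) / n_tr,
               left_prop = mean(lefts) / n_tr,
               right_prop = mean(rights) / n_tr,
               modal_stay_count = as.integer(names(sort(table(stays),
                                                        decreasing = TRUE))[1L]))
  })
  do.call(rbind, rows)
}
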