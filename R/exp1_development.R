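#' Configuration for the developmental (loss-of-optimism) simulation
#'
#' A cohort of agents lives through an in-silico childhood: each year the
#' agent experiences one valence/arousal event per week, infers at the
#' upper level whether it is in an optimistic or pessimistic state, and
#' accumulates Dirichlet counts on the optimism prior (d) and on the
#' arousal likelihood mapping (a2).
#'
#' @param n_agents number of agents in a cohort (default 200).
#' @param obs_level_trials observation-level trials per state-level trial:
#'   52 weekly events per year.
#' @param state_level_trials state-level trials: 5 years of childhood.
#' @param p_negative probability a weekly event is negatively valenced.
#'   `NULL` (the default) draws one value per agent uniformly on (0, 1)
#'   when running a cohort.
#' @param p_high_arousal probability of a high-arousal event given positive
#'   valence.
#' @param p_couple probability of a high-arousal event given negative
#'   valence. Setting `p_couple == p_high_arousal` makes arousal
#'   independent of valence; the default 0.7 couples high arousal to
#'   negative events, the statistically biased environment.
#' @param valence_precision probability, under the optimistic state, of a
#'   positively valenced observation (and symmetrically for the
#'   pessimistic state); this mapping is locked.
#' @param lock_factor concentration multiplier applied to the valence
#'   mapping so that experience cannot move it (default 1000).
#' @param arousal_count0 initial flat concentration per cell of the
#'   learnable arousal mapping (weak prior; default 0.25).
#' @param d_mass initial concentration mass on the optimism prior: counts
#'   start at `optimism_prior * d_mass`. Controls how fast optimism moves.
#' @param optimism_prior innate optimism prior (default `c(0.8, 0.2)`).
#' @param a1_precision level-1 likelihood precision; 1 is the one-to-one
#'   identity mapping.
#' @param seed master seed.
#' @return a list of class `development_config`.
#' @export
development_config <- function(n_agents = 200L, obs_level_trials = 52L,
                               state_level_trials = 5L, p_negative = NULL,
                               p_high_arousal = 0.5, p_couple = 0.7,
                               valence_precision = 0.8, lock_factor = 1000,
                               arousal_count0 = 0.25, d_mass = 1,
                               optimism_prior = c(0.8, 0.2),
                               a1_precision = 1, seed = 1L) {
  cfg <- list(n_agents = as.integer(n_agents),
              obs_level_trials = as.integer(obs_level_trials),
              state_level_trials = as.integer(state_level_trials),
              p_negative = p_negative, p_high_arousal = p_high_arousal,
              p_couple = p_couple, valence_precision = valence_precision,
              lock_factor = lock_factor, arousal_count0 = arousal_count0,
              d_mass = d_mass, optimism_prior = optimism_prior,
              a1_precision = a1_precision, seed = as.integer(seed))
  if (cfg$obs_level_trials < 1L || cfg$state_level_trials < 1L)
    abort("trial counts must be >= 1")
  for (p in c(cfg$p_negative, cfg$p_high_arousal, cfg$p_couple,
              cfg$valence_precision, cfg$a1_precision))
    if (!is.null(p) && !is_prob(p)) abort("probabilities must lie in [0, 1]")
  categorical(cfg$optimism_prior)
  class(cfg) <- "development_config"
  cfg
}

#' Generate a childhood event sequence
#'
#' Samples `state_level_trials * obs_level_trials` weekly events. Valence
#' is negative with probability `p_negative`; arousal is high with
#' probability `p_couple` after a negative event and `p_high_arousal`
#' after a positive one.
#'
#' @param config a [development_config()]; its `p_negative` must be set.
#' @param seed optional seed override; defaults to `config$seed`.
#' @return data.frame with columns `year`, `week`, `valence`
#'   (`"positive"`/`"negative"`), `arousal` (`"high"`/`"low"`).
#' @export
generate_environment <- function(config, seed = config$seed) {
  if (is.null(config$p_negative)) abort("config$p_negative must be set to generate events")
  if (!is.null(seed)) set.seed(seed)
  n <- config$state_level_trials * config$obs_level_trials
  neg <- stats::runif(n) < config$p_negative
  p_high <- ifelse(neg, config$p_couple, config$p_high_arousal)
  high <- stats::runif(n) < p_high
  data.frame(year = rep(seq_len(config$state_level_trials),
                        each = config$obs_level_trials),
             week = rep(seq_len(config$obs_level_trials),
                        times = config$state_level_trials),
             valence = ifelse(neg, "negative", "positive"),
             arousal = ifelse(high, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Run the observation level of the hierarchical model
#'
#' The first level has one state factor per dimension (valence, arousal),
#' a one-to-one likelihood mapping (identity at `a1_precision = 1`), an
#' identity transition and a uniform prior. Its posteriors over states --
#' effectively the event one-hots when the mapping is exact -- become the
#' observations of the state level.
#'
#' @param events event data.frame from [generate_environment()].
#' @param a1_precision diagonal mass of the level-1 likelihood.
#' @return list with matrices `valence` (rows positive/negative) and
#'   `arousal` (rows high/low), one column per event.
#' @export
run_level1 <- function(events, a1_precision = 1) {
  if (NROW(events) == 0L) abort("empty event list")
  p <- a1_precision
  mk <- function(levels) {
    a <- matrix(c(p, 1 - p, 1 - p, p), 2L, 2L) + 1e-16
    generative_model(
      factors = list(state = list(levels = levels, d = c(0.5, 0.5))),
      modalities = list(obs = list(outcomes = levels,
                                   a = dirichlet_counts(a, learnable = FALSE))))
  }
  models <- list(valence = mk(c("positive", "negative")),
                 arousal = mk(c("high", "low")))
  post <- function(model, idx) {
    vapply(idx, function(i) {
      o <- numeric(2); o[i] <- 1
      infer_states(model, list(list(obs = o)))$s[, 1L]
    }, numeric(2))
  }
  v_idx <- ifelse(events$valence == "positive", 1L, 2L)
  a_idx <- ifelse(events$arousal == "high", 1L, 2L)
  out <- list(valence = post(models$valence, v_idx),
              arousal = post(models$arousal, a_idx))
  rownames(out$valence) <- c("positive", "negative")
  rownames(out$arousal) <- c("high", "low")
  out
}

# state-level (level 2) model for the current d and arousal counts
level2_model <- function(config, d_counts, a2_arousal) {
  vp <- config$valence_precision
  a_val <- lock_precision(
    dirichlet_counts(matrix(c(vp, 1 - vp, 1 - vp, vp), 2L, 2L)),
    config$lock_factor)
  generative_model(
    factors = list(optimism = list(levels = c("optimistic", "pessimistic"),
                                   d = dirichlet_counts(d_counts))),
    modalities = list(
      valence = list(outcomes = c("positive", "negative"), a = a_val),
      arousal = list(outcomes = c("high", "low"),
                     a = dirichlet_counts(a2_arousal))),
    horizon = config$obs_level_trials)
}

#' Simulate one agent's in-silico childhood
#'
#' Runs `state_level_trials` years. Within a year the 52 weekly level-1
#' posteriors are presented as sequential observations to the state-level
#' model under an identity transition (the agent stays optimistic or
#' pessimistic within the year). After each year the learnable arousal
#' mapping receives the year's observation/posterior co-occurrence counts
#' and the optimism prior d receives the year's first-timestep posterior.
#'
#' @param config a [development_config()] with `p_negative` set.
#' @param events optional pre-generated event data.frame (bypasses the
#'   internal generator).
#' @return list of class `development_result`: `final_optimism`,
#'   `prop_negative` (empirical), `a2_arousal` (learned, normalised),
#'   `a2_counts`, `d_counts`, `d_trajectory` (2 x years+1),
#'   `optimism_trajectory`, `posteriors` (per-year state posteriors).
#' @export
run_development <- function(config, events = NULL) {
  if (is.null(events)) events <- generate_environment(config)
  l1 <- run_level1(events, config$a1_precision)
  d <- dirichlet_counts(config$optimism_prior * config$d_mass)
  a2 <- dirichlet_counts(matrix(config$arousal_count0, 2L, 2L))
  years <- sort(unique(events$year))
  d_traj <- matrix(NA_real_, 2L, length(years) + 1L)
  d_traj[, 1L] <- d
  posteriors <- vector("list", length(years))

  for (y in seq_along(years)) {
    idx <- which(events$year == years[y])
    obs <- lapply(idx, function(i) list(valence = l1$valence[, i],
                                        arousal = l1$arousal[, i]))
    model <- level2_model(config, d, a2)
    belief <- infer_states(model, obs)
    a2 <- update_a(a2, l1$arousal[, idx, drop = FALSE], belief$s)
    d <- update_d(d, belief$s[, 1L])
    d_traj[, y + 1L] <- d
    posteriors[[y]] <- belief$s
  }

  a2n <- normalize_counts(a2)
  dimnames(a2n) <- list(arousal = c("high", "low"),
                        optimism = c("optimistic", "pessimistic"))
  structure(list(final_optimism = optimism_level(d),
                 prop_negative = mean(events$valence == "negative"),
                 a2_arousal = a2n, a2_counts = a2, d_counts = d,
                 d_trajectory = d_traj,
                 optimism_trajectory = apply(d_traj, 2L, function(x) x[1] / sum(x)),
                 posteriors = posteriors, config = config),
            class = "development_result")
}

#' @export
print.development_result <- function(x, ...) {
  cat("<development_result> optimism", format(x$final_optimism, digits = 3),
      "after", ncol(x$d_trajectory) - 1L, "years;",
      format(100 * x$prop_negative, digits = 3), "% negative events\n")
  invisible(x)
}

#' Simulate a developmental cohort
#'
#' Runs [run_development()] for `n_agents` agents on independent seeded
#' streams. When `config$p_negative` is `NULL` each agent's negative-event
#' probability is drawn uniformly on (0, 1), covering the exposure range.
#'
#' @param config a [development_config()].
#' @return data.frame with one row per agent: `agent`, `seed`,
#'   `p_negative` (target), `prop_negative` (empirical), `optimism`,
#'   `a2_high_given_optimistic`, `a2_high_given_pessimistic`,
#'   `a2_flatness` (max deviation of the learned arousal mapping from
#'   uniform).
#' @export
run_cohort <- function(config) {
  if (config$n_agents < 2L) abort("a cohort needs n_agents >= 2")
  set.seed(config$seed)
  p_neg <- if (is.null(config$p_negative)) stats::runif(config$n_agents)
           else rep_len(config$p_negative, config$n_agents)
  rows <- lapply(seq_len(config$n_agents), function(i) {
    cfg_i <- config
    cfg_i$p_negative <- p_neg[i]
    cfg_i$seed <- derive_seed(config$seed, i)
    res <- run_development(cfg_i)
    data.frame(agent = i, seed = cfg_i$seed, p_negative = p_neg[i],
               prop_negative = res$prop_negative,
               optimism = res$final_optimism,
               a2_high_given_optimistic = res$a2_arousal["high", "optimistic"],
               a2_high_given_pessimistic = res$a2_arousal["high", "pessimistic"],
               a2_flatness = max(abs(res$a2_arousal - 0.5)))
  })
  do.call(rbind, rows)
}
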