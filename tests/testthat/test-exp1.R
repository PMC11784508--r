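test_that("the event generator respects valence probabilities and the seed", {
  cfg <- development_config(p_negative = 1, seed = 3)
  ev <- generate_environment(cfg)
  expect_equal(nrow(ev), 52 * 5)
  expect_true(all(ev$valence == "negative"))

  cfg2 <- development_config(obs_level_trials = 2000L, state_level_trials = 5L,
                             p_negative = 0.5, p_couple = 0.5, seed = 4)
  ev2 <- generate_environment(cfg2)
  expect_equal(mean(ev2$valence == "negative"), 0.5, tolerance = 0.02)

  ev3a <- generate_environment(development_config(p_negative = 0.4, seed = 9))
  ev3b <- generate_environment(development_config(p_negative = 0.4, seed = 9))
  expect_identical(ev3a, ev3b)
})

test_that("arousal couples to valence through p_couple", {
  cfg <- development_config(obs_level_trials = 3000L, p_negative = 0.5,
                            p_couple = 0.9, p_high_arousal = 0.2, seed = 5)
  ev <- generate_environment(cfg)
  expect_equal(mean(ev$arousal[ev$valence == "negative"] == "high"), 0.9,
               tolerance = 0.03)
  expect_equal(mean(ev$arousal[ev$valence == "positive"] == "high"), 0.2,
               tolerance = 0.03)
})

test_that("level-1 posteriors reproduce the event one-hots under the identity mapping", {
  ev <- data.frame(year = 1, week = 1:2,
                   valence = c("negative", "positive"),
                   arousal = c("high", "low"))
  l1 <- run_level1(ev)
  expect_equal(l1$valence[, 1], c(positive = 0, negative = 1), tolerance = 1e-6)
  expect_equal(l1$valence[, 2], c(positive = 1, negative = 0), tolerance = 1e-6)
  expect_equal(l1$arousal[, 1], c(high = 1, low = 0), tolerance = 1e-6)
  expect_error(run_level1(ev[0, ]), "empty")
})

test_that("a perturbed level-1 likelihood matches the exact Bayes oracle", {
  ev <- data.frame(year = 1, week = 1, valence = "negative", arousal = "low")
  l1 <- run_level1(ev, a1_precision = 0.9)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(as.numeric(l1$valence[, 1]),
               oracle_bayes_posterior(list(A), c(0.5, 0.5), list(c(0, 1))),
               tolerance = 1e-3)
})

test_that("all-negative childhoods lose optimism and all-positive ones keep it", {
  res_neg <- run_development(development_config(p_negative = 1, seed = 5))
  expect_lt(res_neg$final_optimism, 0.8)
  res_pos <- run_development(development_config(p_negative = 0, seed = 5))
  expect_gte(res_pos$final_optimism, 0.8)
  # optimism level stays in [0, 1] along the trajectory
  expect_true(all(res_neg$optimism_trajectory >= 0 &
                  res_neg$optimism_trajectory <= 1))
  # learned arousal mapping columns are categorical
  expect_equal(colSums(res_neg$a2_arousal), c(optimistic = 1, pessimistic = 1))
})

test_that("high-coupling negative environments learn an anxious arousal mapping", {
  res <- run_development(development_config(p_negative = 0.9, p_couple = 0.9,
                                            p_high_arousal = 0.5, seed = 7))
  expect_gt(res$a2_arousal["high", "pessimistic"],
            res$a2_arousal["high", "optimistic"])
  expect_gt(res$a2_arousal["high", "pessimistic"], 0.65)
})

test_that("balanced uncorrelated exposure leaves the arousal mapping near flat", {
  for (seed in c(5, 17)) {
    res <- run_development(development_config(p_negative = 0.5, p_couple = 0.5,
                                              p_high_arousal = 0.5, seed = seed))
    expect_lt(max(abs(res$a2_arousal - 0.5)), 0.15)
  }
})

test_that("front-loaded negative years depress optimism more than back-loaded ones", {
  cfg <- development_config(p_negative = 0.5, seed = 1)
  n_year <- cfg$obs_level_trials
  mk_events <- function(neg_years) {
    do.call(rbind, lapply(1:5, function(y) {
      neg <- y %in% neg_years
      # moderately biased years so the prior retains influence
      set.seed(100 + y)
      v <- ifelse(runif(n_year) < ifelse(neg, 0.75, 0.25), "negative", "positive")
      data.frame(year = y, week = seq_len(n_year), valence = v,
                 arousal = rep(c("high", "low"), length.out = n_year))
    }))
  }
  front <- run_development(cfg, events = mk_events(1:2))
  back <- run_development(cfg, events = mk_events(4:5))
  expect_lt(front$final_optimism, back$final_optimism)
})

test_that("cohorts reproduce the negative-exposure gradient with spread", {
  cfg <- development_config(n_agents = 60L, seed = 11)
  tab <- run_cohort(cfg)
  expect_equal(nrow(tab), 60L)
  rho <- cor(tab$prop_negative, tab$optimism, method = "spearman")
  expect_lt(rho, -0.5)
  # identical seeds and exposure give identical rows
  cfg2 <- development_config(n_agents = 2L, p_negative = 0.5, seed = 21)
  tab2 <- run_cohort(cfg2)
  tab2$seed <- tab2$seed[1]; tab2$agent <- 1L
  res_a <- run_development(development_config(p_negative = 0.5, seed = tab2$seed[1]))
  expect_equal(tab2$optimism[1], res_a$final_optimism)
  # exposure does not map one-to-one onto optimism: matched proportions spread
  mid <- tab[tab$prop_negative > 0.35 & tab$prop_negative < 0.65, ]
  expect_gt(nrow(mid), 3)
  expect_gt(diff(range(mid$optimism)), 0.05)
})

test_that("final optimism is non-increasing in exposure in expectation", {
  meds <- vapply(c(0.15, 0.5, 0.85), function(p) {
    cfg <- development_config(n_agents = 25L, p_negative = p, seed = 31)
    stats::median(run_cohort(cfg)$optimism)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})
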