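test_that("novelty weights follow the half-inverse-count formula", {
  expect_equal(as.numeric(novelty_weight(matrix(c(1, 1), 2, 1))),
               c(0.25, 0.25))
  W_big <- novelty_weight(matrix(1000, 2, 1))
  expect_equal(as.numeric(W_big), rep(0.00025, 2), tolerance = 1e-12)
  set.seed(5)
  a <- matrix(runif(9, 0.2, 5), 3, 3)
  expect_equal(novelty_weight(a), oracle_W(a), tolerance = 1e-14)
  expect_true(all(novelty_weight(a) >= 0))
  expect_error(novelty_weight(matrix(c(1, 0), 2, 1)), "positive")
})

test_that("expected free energy terms vanish in the fully resolved limit", {
  # deterministic likelihood, huge counts, predicted outcomes = preferences
  C <- c(2, 0)
  pref_dist <- softmax(C)
  counts <- diag(2) * 1e6 + 1e3           # near-deterministic, heavily counted
  model <- generative_model(
    factors = list(state = list(levels = c("a", "b"), d = pref_dist)),
    modalities = list(obs = list(outcomes = c("x", "y"),
                                 a = dirichlet_counts(counts, learnable = TRUE))),
    preferences = list(obs = C))
  b <- list(s = matrix(pref_dist, 2, 1))
  ev <- expected_free_energy(model, structure(b, class = "belief_state"), policy = 1)
  expect_lt(abs(ev$risk), 1e-4)
  expect_lt(abs(ev$ambiguity), 0.02)
  expect_lt(ev$novelty, 0.02)
  expect_lt(abs(ev$G), 0.05)
})

test_that("a flat likelihood yields ambiguity ln 2 regardless of beliefs", {
  model <- generative_model(
    factors = list(state = list(levels = c("a", "b"), d = c(0.5, 0.5))),
    modalities = list(obs = list(outcomes = c("x", "y"),
                                 a = dirichlet_counts(matrix(0.5, 2, 2)))))
  for (s1 in c(0.1, 0.5, 0.9)) {
    ev <- expected_free_energy(model,
                               structure(list(s = matrix(c(s1, 1 - s1), 2, 1)),
                                         class = "belief_state"), policy = 1)
    expect_equal(ev$ambiguity, log(2), tolerance = 1e-9)
  }
})

test_that("G matches independent term-by-term hand evaluation", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  counts <- matrix(c(2, 1, 1, 2), 2, 2)
  s <- c(0.5, 0.5)
  Cw <- c(1, 0)
  model <- generative_model(
    factors = list(state = list(levels = c("a", "b"), d = c(0.5, 0.5))),
    modalities = list(obs = list(outcomes = c("x", "y"),
                                 a = dirichlet_counts(counts, learnable = TRUE))),
    preferences = list(obs = Cw))
  # model's A is the normalised counts; use it for the oracle too
  An <- normalize_counts(counts)
  ev <- expected_free_energy(model,
                             structure(list(s = matrix(s, 2, 1)),
                                       class = "belief_state"), policy = 1)
  or <- oracle_G_terms(unclass(An), s, Cw, a_counts = counts)
  expect_equal(ev$risk, or$risk, tolerance = 1e-10)
  expect_equal(ev$ambiguity, or$ambiguity, tolerance = 1e-10)
  expect_equal(ev$novelty, or$novelty, tolerance = 1e-10)
  expect_equal(ev$G, or$risk + or$ambiguity - or$novelty, tolerance = 1e-10)
})

test_that("locked modalities contribute no novelty", {
  counts <- dirichlet_counts(matrix(c(2, 1, 1, 2), 2, 2), learnable = FALSE)
  model <- generative_model(
    factors = list(state = list(levels = c("a", "b"), d = c(0.5, 0.5))),
    modalities = list(obs = list(outcomes = c("x", "y"), a = counts)))
  ev <- expected_free_energy(model,
                             structure(list(s = matrix(c(0.5, 0.5), 2, 1)),
                                       class = "belief_state"), policy = 1)
  expect_identical(ev$novelty, 0)
})

test_that("novelty vanishes as counts grow and G reduces to risk plus ambiguity", {
  set.seed(9)
  a_small <- matrix(runif(4, 0.5, 2), 2, 2)
  s <- c(0.4, 0.6)
  mk <- function(scale) generative_model(
    factors = list(state = list(levels = c("a", "b"), d = c(0.5, 0.5))),
    modalities = list(obs = list(outcomes = c("x", "y"),
                                 a = dirichlet_counts(a_small * scale, learnable = TRUE))),
    preferences = list(obs = c(1, -1)))
  bel <- structure(list(s = matrix(s, 2, 1)), class = "belief_state")
  novs <- vapply(c(1, 10, 1e4), function(sc)
    expected_free_energy(mk(sc), bel, policy = 1)$novelty, numeric(1))
  expect_true(all(diff(novs) < 0))
  expect_lt(novs[3], 1e-3)
  ev <- expected_free_energy(mk(1e8), bel, policy = 1)
  expect_equal(ev$G, sum(ev$risk + ev$ambiguity), tolerance = 1e-6)
})

test_that("policy posteriors decrease in G and respect shift invariance of preferences", {
  p <- policy_posterior(c(1, 2, 3))
  expect_equal(p, softmax(-c(1, 2, 3)))
  expect_true(all(diff(p) < 0))
  expect_equal(policy_posterior(c(0, 0)), c(0.5, 0.5))
  expect_equal(policy_posterior(c(0, 1e6))[1], 1, tolerance = 1e-12)

  # adding a constant to every preference weight leaves the posterior unchanged
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  mk <- function(shift) generative_model(
    factors = list(state = list(levels = c("a", "b"), d = c(0.5, 0.5))),
    modalities = list(obs = list(outcomes = c("x", "y"),
                                 a = dirichlet_counts(A, learnable = FALSE))),
    preferences = list(obs = c(2, -1) + shift))
  bel1 <- structure(list(s = matrix(c(0.9, 0.1), 2, 1)), class = "belief_state")
  bel2 <- structure(list(s = matrix(c(0.2, 0.8), 2, 1)), class = "belief_state")
  post <- function(shift) policy_posterior(c(
    expected_free_energy(mk(shift), bel1, policy = 1)$G,
    expected_free_energy(mk(shift), bel2, policy = 2)$G))
  expect_equal(post(0), post(7.5), tolerance = 1e-12)
})

test_that("predicted outcomes closer to preferences in KL earn higher posterior probability", {
  A <- diag(2) + 1e-16
  model <- generative_model(
    factors = list(state = list(levels = c("a", "b"), d = c(0.5, 0.5))),
    modalities = list(obs = list(outcomes = c("x", "y"),
                                 a = dirichlet_counts(A, learnable = FALSE))),
    preferences = list(obs = c(3, 0)))
  near <- structure(list(s = matrix(c(0.9, 0.1), 2, 1)), class = "belief_state")
  far <- structure(list(s = matrix(c(0.5, 0.5), 2, 1)), class = "belief_state")
  G <- c(expected_free_energy(model, near, policy = 1)$G,
         expected_free_energy(model, far, policy = 2)$G)
  post <- policy_posterior(G)
  expect_gt(post[1], post[2])
})

test_that("action selection is deterministic under argmax and reproducible under seed", {
  expect_equal(select_action(c(1, 0, 0), "sample"), 1L)
  expect_equal(select_action(c(1, 0, 0), "argmax"), 1L)
  expect_equal(select_action(c(0.5, 0.5), "argmax"), 1L)  # lowest-index tie-break
  set.seed(33); a1 <- select_action(c(0.25, 0.25, 0.25, 0.25), "sample")
  set.seed(33); a2 <- select_action(c(0.25, 0.25, 0.25, 0.25), "sample")
  expect_identical(a1, a2)
})
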