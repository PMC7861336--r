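test_that("the descending empirical prior is the predictive stimulus density", {
  m2 <- build_level2_model()
  ss <- enumerate_scene_states()
  # certain scene, fixating a quadrant holding its first RDM
  s <- which(ss$scene == 1 & ss$q1 == 1 & ss$q2 == 3)
  d <- empirical_prior_down(one_hot_vec(s, 48), 2, m2$A[[1]])
  expect_equal(d, c(0, 1, 0, 0, 0), tolerance = 1e-12)  # one-hot on UP
  # uniform scene beliefs: matches brute-force marginalization
  for (loc in c(2, 4)) {
    d <- empirical_prior_down(rep(1 / 48, 48), loc, m2$A[[1]])
    brute <- numeric(5)
    for (s in 1:48) {
      brute <- brute + (1 / 48) * m2$A[[1]][, s, loc]
    }
    expect_equal(d, brute / sum(brute), tolerance = 1e-12)
    expect_equal(sum(d), 1, tolerance = 1e-9)
  }
})

test_that("inferred observations ascend unchanged and flagged", {
  o <- ascend_inferred_observation(c(0, 1, 0, 0, 0))
  expect_equal(as.numeric(o), c(0, 1, 0, 0, 0))
  g <- ascend_inferred_observation(c(0.1, 0.4, 0.3, 0.1, 0.1))
  expect_equal(as.numeric(g), c(0.1, 0.4, 0.3, 0.1, 0.1))
  expect_true(attr(g, "inferred"))
  expect_error(ascend_inferred_observation(c(0.5, 0.2)), "sum to 1")
})

test_that("overwhelming urgency breaks sampling at the first step", {
  m1 <- build_level1_model(p = 2, kappa = 10)
  set.seed(21)
  for (i in 1:10) {
    ep <- run_level1_episode(m1, 2L, rep(0.2, 5), p_process = 2)
    expect_equal(ep$break_time, 1L)
  }
})

test_that("uninformative observations leave the empirical prior in place", {
  # near-zero precision: motion samples are uniform over the four directions
  # and carry no information beyond the presence of an RDM, so a
  # direction-supported empirical prior passes through (nearly) unchanged
  m1 <- build_level1_model(p = 1e-4)
  set.seed(22)
  kl <- numeric(100)
  for (i in 1:100) {
    prior <- c(0, random_prob(4))
    ep <- run_level1_episode(m1, sample.int(4, 1) + 1L, prior,
                             p_process = 1e-4)
    kl[i] <- kl_divergence(ep$posterior, prior)
  }
  expect_lt(mean(kl), 0.05)
})

test_that("without urgency the episode runs to the 20-step cap", {
  # kappa = 0: Break never carries lower expected free energy while any
  # epistemic value remains, so sampling runs to the horizon
  m1 <- build_level1_model(p = 0.5, kappa = 0)
  set.seed(23)
  for (i in 1:5) {
    ep <- run_level1_episode(m1, 3L, rep(0.2, 5), p_process = 0.5)
    expect_equal(ep$break_time, 20L)
    expect_equal(length(ep$policy_differential), 20)
  }
})

test_that("break times never exceed the horizon and differentials are recorded", {
  set.seed(24)
  m1 <- build_level1_model(p = 1)
  for (i in 1:20) {
    ep <- run_level1_episode(m1, sample.int(5, 1), random_prob(5),
                             p_process = 1)
    expect_lte(ep$break_time, 20L)
    expect_gte(ep$break_time, 1L)
    expect_equal(nrow(ep$q_pi), ep$break_time)
    expect_equal(sum(ep$posterior), 1, tolerance = 1e-9)
  }
})

test_that("a certain prior triggers categorization before any fixation", {
  set.seed(25)
  for (i in 1:5) {
    tr <- run_trial(list(p_model = 1, prior_scene = 2, prior_strength = 1,
                         true_scene = 2), seed = 250 + i)
    expect_equal(tr$latency, 1L)
    expect_equal(tr$choice, 2L)
    expect_true(tr$correct)
  }
  # with a certain but wrong prior the immediate guess is incorrect
  tr <- run_trial(list(p_model = 1, prior_scene = 2, prior_strength = 1,
                       true_scene = 4), seed = 99)
  expect_equal(tr$latency, 1L)
  expect_false(tr$correct)
})

test_that("precise agents with flat priors categorize correctly", {
  set.seed(26)
  correct <- logical(20)
  for (i in 1:20) {
    tr <- run_trial(list(p_model = 5), seed = 500 + i)
    expect_true(tr$responded)
    correct[i] <- tr$correct
    # feedback present iff a choice location was fixated, and the trial
    # stops at its first categorization
    last <- tr$steps[[length(tr$steps)]]
    expect_true(last$location %in% 6:9)
    expect_equal(tr$latency, length(tr$steps))
    # break times within every fixation respect the Level-1 horizon
    for (s in tr$steps) {
      if (!is.na(s$break_time)) expect_lte(s$break_time, 20L)
    }
  }
  expect_gte(mean(correct), 0.9)
})

test_that("level separation: the episode interface carries only the empirical prior", {
  # Level 1 never reads Level-2 arrays except through D_empirical, and
  # Level 2 receives only the ascended posterior
  expect_named(formals(run_level1_episode),
               c("model1", "true_direction", "D_empirical", "p_process",
                 "settings", "alpha"))
  m1 <- build_level1_model(p = 2)
  d <- c(0.1, 0.5, 0.2, 0.1, 0.1)
  set.seed(27)
  a <- run_level1_episode(m1, 2L, d, p_process = 2)
  set.seed(27)
  b <- run_level1_episode(m1, 2L, d, p_process = 2)
  expect_identical(a, b)
})

test_that("trial records are reproducible under a seed", {
  a <- run_trial(list(p_model = 1.5), seed = 77)
  b <- run_trial(list(p_model = 1.5), seed = 77)
  expect_identical(a$scene$index, b$scene$index)
  expect_identical(a$latency, b$latency)
  expect_identical(vapply(a$steps, `[[`, numeric(1), "location"),
                   vapply(b$steps, `[[`, numeric(1), "location"))
  expect_equal(a$scene_beliefs, b$scene_beliefs, tolerance = 1e-12)
})
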