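no_actions <- function(nf = 1) matrix(integer(0), 0, nf)

test_that("single-step state estimation reproduces exact Bayes", {
  # uniform prior, identity likelihood: posterior equals the observation
  m <- random_small_model(n_o = 4, n_s = 4)
  m$A <- list(diag(4))
  m$A_flat <- list(diag(4))
  m$A_keep <- list(list(diag(4)))
  m$H_A <- list(rep(0, 4))
  m$D <- list(rep(0.25, 4))
  qs <- infer_states(m, list(list(c(0, 0, 1, 0))), no_actions())
  expect_equal(qs[[1]][[1]], c(0, 0, 1, 0), tolerance = 1e-5)

  # all combinations of one-hot observation and permuted deterministic
  # likelihood on a 4-state model
  set.seed(11)
  for (shift in 0:3) {
    A <- diag(4)[, (0:3 + shift) %% 4 + 1]
    mm <- new_level_model(A = list(A), B = list(array(diag(4), c(4, 4, 1))),
                          C = list(matrix(0, 4, 2)), D = list(random_prob(4)),
                          policies = matrix(1L, 1, 1), gamma = 1, T = 2)
    for (o in 1:4) {
      obs <- list(list(one_hot_vec(o, 4)))
      got <- infer_states(mm, obs, no_actions())[[1]][[1]]
      want <- brute_posterior(A, mm$D[[1]], obs[[1]][[1]])$posterior
      expect_equal(got, want, tolerance = 1e-5)
    }
  }

  # noisy likelihoods against the enumeration oracle
  for (i in 1:30) {
    mm <- random_small_model(n_o = 3, n_s = 5)
    o <- one_hot_vec(sample.int(3, 1), 3)
    got <- infer_states(mm, list(list(o)), no_actions())[[1]][[1]]
    want <- brute_posterior(mm$A[[1]], mm$D[[1]], o)$posterior
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("multi-step estimation matches the exact categorical filter", {
  set.seed(12)
  for (i in 1:10) {
    mm <- random_small_model(n_o = 3, n_s = 4, T = 4, identity_B = FALSE)
    obs <- lapply(1:3, function(t) list(one_hot_vec(sample.int(3, 1), 3)))
    actions <- matrix(1L, 3, 1)
    got <- infer_states(mm, obs, actions)
    want <- brute_filter(mm$A[[1]], mm$B[[1]][, , 1], mm$D[[1]],
                         lapply(obs, `[[`, 1))
    for (t in 1:3) expect_equal(got[[t]][[1]], want[[t]], tolerance = 1e-5)
    # the extra element is the one-step-ahead prediction
    expect_equal(got[[4]][[1]], as.vector(mm$B[[1]][, , 1] %*% want[[3]]),
                 tolerance = 1e-5)
  }
})

test_that("repeated consistent observations contract onto the truth", {
  m <- build_level1_model(p = 2)
  truth <- 3L
  obs <- list()
  kl <- numeric(8)
  for (t in 1:8) {
    obs[[t]] <- list(one_hot_vec(truth, 5), c(1, 0))
    qs <- infer_states(m, obs, matrix(1L, t - 1, 2, byrow = TRUE))
    kl[t] <- kl_divergence(qs[[t]][[1]], one_hot_vec(truth, 5))
  }
  expect_true(all(diff(kl) <= 1e-9))
})

test_that("non-convergence returns beliefs with a warning, not an error", {
  m <- build_level1_model(p = 0.5)
  obs <- list(list(one_hot_vec(2, 5), c(1, 0)))
  expect_warning(
    infer_states(m, obs, no_actions(2),
                 inference_settings(max_iters = 1, tol = 1e-15)),
    "converge")
})

test_that("free energy equals negative log evidence at the exact posterior", {
  # worked case: identity likelihood, uniform 2-state prior, one-hot
  # observation; evidence = 1/2 so F = log(2)
  m <- new_level_model(A = list(diag(2)), B = list(array(diag(2), c(2, 2, 1))),
                       C = list(matrix(0, 2, 2)), D = list(c(0.5, 0.5)),
                       policies = matrix(1L, 1, 1), gamma = 1, T = 2)
  obs <- list(list(c(1, 0)))
  qs <- list(list(c(1, 0)))
  expect_equal(free_energy_policy(qs, obs, m, no_actions()), log(2),
               tolerance = 1e-6)

  set.seed(13)
  for (i in 1:30) {
    mm <- random_small_model(n_o = 3, n_s = 4)
    mm$D <- list(random_prob(4, min_mass = 0.2))
    o <- one_hot_vec(sample.int(3, 1), 3)
    br <- brute_posterior(mm$A[[1]], mm$D[[1]], o)
    Fexact <- free_energy_policy(list(list(br$posterior)), list(list(o)),
                                 mm, no_actions())
    expect_equal(Fexact, -log(br$evidence), tolerance = 1e-5)
    # the bound: any perturbed belief has higher free energy
    for (w in c(0.05, 0.3, 0.9)) {
      perturbed <- (1 - w) * br$posterior + w * rep(0.25, 4)
      Fp <- free_energy_policy(list(list(perturbed)), list(list(o)),
                               mm, no_actions())
      expect_gte(Fp, -log(br$evidence) - 1e-6)
    }
    # and the bound holds with a sizable gap for a strong perturbation
    Fu <- free_energy_policy(list(list(rep(0.25, 4))), list(list(o)),
                             mm, no_actions())
    expect_gte(Fu, Fexact - 1e-6)
  }
})

test_that("expected free energy components match brute-force enumeration", {
  # deterministic likelihood, resolved beliefs, flat preferences:
  # no ambiguity and nothing left to learn
  m <- new_level_model(A = list(diag(4)), B = list(array(diag(4), c(4, 4, 1))),
                       C = list(matrix(0, 4, 2)), D = list(rep(0.25, 4)),
                       policies = matrix(1L, 1, 1), gamma = 1, T = 2)
  g <- expected_free_energy(m, list(c(1, 0, 0, 0)), 1)
  expect_equal(g$epistemic, 0, tolerance = 1e-9)
  expect_equal(g$ambiguity, 0, tolerance = 1e-9)
  # uniform beliefs through the identity channel: epistemic value is the
  # full prior entropy log(4)
  g4 <- expected_free_energy(m, list(rep(0.25, 4)), 1)
  expect_equal(g4$epistemic, log(4), tolerance = 1e-9)

  set.seed(14)
  for (i in 1:200) {
    two_factor <- i %% 3 == 0
    if (two_factor) {
      A <- array(stats::runif(3 * 3 * 2, 0.05, 1), c(3, 3, 2))
      Af <- sweep(matrix(A, 3), 2, colSums(matrix(A, 3)), "/")
      A <- array(Af, c(3, 3, 2))
      mm <- new_level_model(
        A = list(A),
        B = list(array(diag(3), c(3, 3, 1)), array(diag(2), c(2, 2, 1))),
        C = list(matrix(stats::rnorm(3 * 2), 3, 2)),
        D = list(random_prob(3), random_prob(2)),
        policies = matrix(1L, 1, 2), gamma = 1, T = 2)
      beliefs <- list(random_prob(3), random_prob(2))
      q_joint <- as.vector(outer(beliefs[[1]], beliefs[[2]]))
      A_brute <- Af
    } else {
      mm <- random_small_model(n_o = 4, n_s = 5)
      beliefs <- list(random_prob(5))
      q_joint <- beliefs[[1]]
      A_brute <- mm$A[[1]]
    }
    tau <- sample.int(2, 1)
    g <- expected_free_energy(mm, beliefs, tau)
    want <- brute_efe(A_brute, q_joint, mm$C[[1]][, tau])
    expect_equal(g$risk, want$risk, tolerance = 1e-6)
    expect_equal(g$ambiguity, want$ambiguity, tolerance = 1e-6)
    expect_equal(g$epistemic, want$epistemic, tolerance = 1e-6)
    expect_equal(g$instrumental, want$instrumental, tolerance = 1e-6)
    # decomposition identity: risk + ambiguity = -epistemic - instrumental
    expect_equal(g$risk + g$ambiguity, -g$epistemic - g$instrumental,
                 tolerance = 1e-9)
    expect_gte(g$ambiguity, -1e-12)
    expect_gte(g$epistemic, -1e-9)
  }
  expect_error(expected_free_energy(m, list(rep(0.25, 4)), 5), "horizon")
})

test_that("the policy posterior applies gamma to G only", {
  expect_equal(policy_posterior(c(1, 1, 1), c(2, 2, 2), 512), rep(1 / 3, 3))
  # gamma = 0: G is ignored
  expect_equal(policy_posterior(c(0, log(3)), c(5, -5), 0),
               softmax_vec(c(0, -log(3))))
  # logistic of 512 * 0.01 = 5.12
  q <- policy_posterior(c(1, 1), c(0, 0.01), 512)
  expect_equal(q, c(1, exp(-5.12)) / (1 + exp(-5.12)), tolerance = 1e-9)
  expect_equal(q[1], 0.994, tolerance = 1e-3)
  expect_error(policy_posterior(c(1, 2), c(1, 2, 3), 1), "length")
})

test_that("action selection honors the posterior and the precision regimes", {
  expect_equal(select_action(c(0, 1, 0)), 2L)
  set.seed(15)
  draws <- replicate(1e4, select_action(c(0.5, 0.5)))
  expect_lt(abs(mean(draws == 1) - 0.5), 3 * sqrt(0.25 / 1e4))
  set.seed(16)
  a <- replicate(20, select_action(c(0.3, 0.7)))
  set.seed(16)
  b <- replicate(20, select_action(c(0.3, 0.7)))
  expect_identical(a, b)
  # deterministic regime picks the maximum, ties broken uniformly
  expect_equal(select_action(c(0.2, 0.7, 0.1), alpha = Inf), 2L)
  set.seed(17)
  ties <- replicate(200, select_action(c(0.5, 0.5), alpha = Inf))
  expect_true(all(sort(unique(ties)) == c(1L, 2L)))
})

test_that("Bayesian model averaging mixes policy-conditioned beliefs", {
  b <- list(list(c(1, 0)), list(c(0, 1)))
  expect_equal(bayesian_model_average(b, c(1, 0))[[1]], c(1, 0))
  expect_equal(bayesian_model_average(b, c(0.5, 0.5))[[1]], c(0.5, 0.5))
  set.seed(18)
  b2 <- list(list(random_prob(4)), list(random_prob(4)), list(random_prob(4)))
  q <- random_prob(3)
  avg <- bayesian_model_average(b2, q)[[1]]
  expect_equal(sum(avg), 1, tolerance = 1e-9)
  expect_equal(avg, q[1] * b2[[1]][[1]] + q[2] * b2[[2]][[1]] +
                 q[3] * b2[[3]][[1]], tolerance = 1e-9)
})
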