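# Shared fixtures and independent brute-force oracles used across the suite.
# The oracles enumerate joint (outcome, state) combinations directly and stay
# independent of the package's vectorized implementations.

# Random probability vector with entries bounded away from zero (keeps the
# exp(-16) log floor negligible relative to the tested tolerances).
random_prob <- function(n, min_mass = 0.05) {
  x <- stats::runif(n, min = min_mass, max = 1)
  x / sum(x)
}

# Random single-factor generative model: likelihood (n_o x n_s), identity or
# random-stochastic transitions, random preferences and prior.
random_small_model <- function(n_o = 3, n_s = 4, T = 3, gamma = 1,
                               identity_B = TRUE) {
  A <- matrix(stats::runif(n_o * n_s, 0.05, 1), n_o, n_s)
  A <- sweep(A, 2, colSums(A), "/")
  B <- if (identity_B) array(diag(n_s), c(n_s, n_s, 1)) else {
    M <- matrix(stats::runif(n_s * n_s, 0.05, 1), n_s, n_s)
    array(sweep(M, 2, colSums(M), "/"), c(n_s, n_s, 1))
  }
  C <- matrix(stats::rnorm(n_o * T), n_o, T)
  D <- random_prob(n_s)
  new_level_model(A = list(A), B = list(B), C = list(C), D = list(D),
                  policies = matrix(1L, 1, 1), gamma = gamma, T = T)
}

# Exact single-step posterior and evidence by enumeration.
brute_posterior <- function(A, D, o) {
  lik <- as.vector(crossprod(A, o)) # mixture likelihood per state
  joint <- D * lik
  list(posterior = joint / sum(joint), evidence = sum(joint))
}

# Exact filtering posteriors over a sequence of one-hot observations under a
# single factor with transition B (enumeration over state paths is unneeded:
# the categorical filter is exact, computed here step by step from scratch).
brute_filter <- function(A, B, D, obs) {
  q <- D
  out <- list()
  for (t in seq_along(obs)) {
    prior <- if (t == 1) D else as.vector(B %*% q)
    joint <- prior * as.vector(crossprod(A, obs[[t]]))
    q <- joint / sum(joint)
    out[[t]] <- q
  }
  out
}

# Expected-free-energy components by direct enumeration over (o, s),
# including the epistemic term in its expected-posterior-divergence form.
brute_efe <- function(A, q, c_log_pref) {
  n_o <- nrow(A)
  c_tilde <- exp(c_log_pref - max(c_log_pref))
  c_tilde <- c_tilde / sum(c_tilde)
  o_pred <- as.vector(A %*% q)
  risk <- 0
  for (o in seq_len(n_o)) {
    if (o_pred[o] > 0) {
      risk <- risk + o_pred[o] *
        (log(o_pred[o]) - log(c_tilde[o] + exp(-16)))
    }
  }
  ambiguity <- 0
  for (s in seq_along(q)) {
    for (o in seq_len(n_o)) {
      if (A[o, s] > 0) ambiguity <- ambiguity - q[s] * A[o, s] * log(A[o, s])
    }
  }
  epistemic <- 0
  for (o in seq_len(n_o)) {
    if (o_pred[o] <= 0) next
    post <- A[o, ] * q / o_pred[o]
    kl <- 0
    for (s in seq_along(q)) {
      if (post[s] > 0) kl <- kl + post[s] * (log(post[s]) - log(q[s]))
    }
    epistemic <- epistemic + o_pred[o] * kl
  }
  instrumental <- sum(o_pred * log(c_tilde + exp(-16)))
  list(risk = risk, ambiguity = ambiguity, epistemic = epistemic,
       instrumental = instrumental)
}

one_hot_vec <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}
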