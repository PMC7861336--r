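# Construction of the Level-1 (motion sampling) and Level-2 (scene inference)
# generative models.
#
# A level model bundles, for one layer of the hierarchy:
#   A: per-modality likelihood arrays, dim (outcomes, factor-1 states,
#      factor-2 states); columns are conditional outcome distributions.
#   B: per-factor transition arrays, dim (next state, previous state, action).
#   C: per-modality preference schedules, log-preferences (nats) x time.
#   D: per-factor initial state priors.
#   policies: one row per single-step policy, one action index per factor.
#   gamma: policy precision (inverse temperature over expected free energy).
#   T: temporal horizon of the level.

#' Construct a single-level generative model
#'
#' Low-level constructor used by [build_level1_model()] and
#' [build_level2_model()]; validates normalization and shapes and precomputes
#' flattened likelihoods and per-state outcome entropies used by the inference
#' engine.
#'
#' @param A List of likelihood arrays (outcomes x states of every factor).
#' @param B List of per-factor transition arrays (next, previous, action).
#' @param C List of per-modality preference matrices (outcomes x time, nats).
#' @param D List of per-factor initial-belief probability vectors.
#' @param policies Integer matrix, one row per policy, one action per factor.
#' @param gamma Policy precision (unitless inverse temperature).
#' @param T Temporal horizon (time steps, >= 1).
#' @param modalities,factors Optional character labels.
#' @return Object of class `level_model`.
#' @export
new_level_model <- function(A, B, C, D, policies, gamma, T,
                            modalities = NULL, factors = NULL) {
  n_states <- vapply(D, length, integer(1))
  n_out <- vapply(A, function(a) dim(a)[1], integer(1))
  for (m in seq_along(A)) {
    d <- dim(A[[m]])
    if (!identical(as.integer(d[-1]), as.integer(n_states))) {
      stop("likelihood state dimensions must match D", call. = FALSE)
    }
    cs <- colSums(flatten_likelihood(A[[m]]))
    if (any(abs(cs - 1) > 1e-9)) {
      stop("likelihood columns must sum to 1", call. = FALSE)
    }
  }
  for (f in seq_along(B)) {
    d <- dim(B[[f]])
    if (d[1] != n_states[f] || d[2] != n_states[f]) {
      stop("transition dimensions must match the state space", call. = FALSE)
    }
    for (u in seq_len(d[3])) {
      if (any(abs(colSums(B[[f]][, , u]) - 1) > 1e-9)) {
        stop("transition columns must sum to 1", call. = FALSE)
      }
    }
    assert_prob(D[[f]], arg = "D")
  }
  for (m in seq_along(C)) {
    if (nrow(C[[m]]) != n_out[m] || any(!is.finite(C[[m]]))) {
      stop("preference schedules must be finite with one row per outcome",
           call. = FALSE)
    }
  }
  if (T < 1) stop("horizon 'T' must be >= 1", call. = FALSE)
  policies <- matrix(as.integer(policies), nrow = nrow(policies))
  for (f in seq_along(B)) {
    if (any(policies[, f] < 1 | policies[, f] > dim(B[[f]])[3])) {
      stop("policy actions must index valid transition matrices", call. = FALSE)
    }
  }
  m <- list(
    A = A, B = B, C = C, D = D, policies = policies,
    gamma = gamma, T = as.integer(T),
    n_states = n_states, n_outcomes = n_out,
    A_flat = lapply(A, flatten_likelihood),
    H_A = lapply(A, ambiguity_vector),
    modalities = modalities, factors = factors
  )
  # Per-factor contraction kernels for fast evidence computation (two-factor
  # models): A_keep[[m]][[f]] %*% (other factor's belief) reshapes to the
  # outcomes x states-of-f matrix.
  m$A_keep <- lapply(A, function(a) {
    d <- dim(a)
    if (length(d) == 3) {
      list(matrix(a, nrow = d[1] * d[2]),                      # keep factor 1
           matrix(aperm(a, c(1, 3, 2)), nrow = d[1] * d[3]))   # keep factor 2
    } else {
      list(matrix(a, nrow = d[1]))
    }
  })
  class(m) <- "level_model"
  m
}

#' @export
print.level_model <- function(x, ...) {
  cat("<level_model>\n")
  cat("  factors:   ", paste(sprintf("%s[%d]",
      if (is.null(x$factors)) seq_along(x$D) else x$factors,
      x$n_states), collapse = ", "), "\n")
  cat("  modalities:", paste(sprintf("%s[%d]",
      if (is.null(x$modalities)) seq_along(x$A) else x$modalities,
      x$n_outcomes), collapse = ", "), "\n")
  cat("  policies:  ", nrow(x$policies), " single-step; gamma = ", x$gamma,
      "; horizon T = ", x$T, "\n", sep = "")
  invisible(x)
}

#' Build the Level-1 (motion sampling) generative model
#'
#' Level 1 models the contents of a single fixation. Hidden factors: the
#' motion direction of the fixated stimulus (`Null, UP, RIGHT, DOWN, LEFT`;
#' constant within a fixation) and the binary sampling state
#' (`Keep-sampling` / `Break-sampling`; controllable, with `Break` an
#' absorbing sink that terminates the fixation). Modalities: the motion
#' observation (conditioned on both factors: the precision-`p` sharpened
#' direction mapping while sampling continues, all mass on `Null` once
#' sampling has been broken) and an unambiguous proprioceptive report of the
#' sampling state. The `Break` preference grows linearly in time
#' (`kappa * (tau - 1)` nats), encoding urgency to stop sampling.
#'
#' @param p Sensory precision of the motion likelihood (> 0); the model analog
#'   of RDM coherence.
#' @param kappa Urgency slope in nats per time step (default 0.005, chosen
#'   once so that fixational dwell times show the inverted-U dependence on
#'   sensory precision; see the methods vignette).
#' @param T1 Temporal horizon of a fixation (default 20 steps).
#' @param gamma Policy precision (default 512; effectively deterministic
#'   selection of the more probable policy).
#' @return A `level_model` with policies `Keep` (action 1) and `Break`
#'   (action 2).
#' @export
build_level1_model <- function(p, kappa = 0.005, T1 = 20, gamma = 512) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0) {
    stop("'p' must be a single positive precision", call. = FALSE)
  }
  sharp <- sharpen_likelihood(diag(5), p, ambiguous = 2:5)
  A1 <- array(0, c(5, 5, 2),
              dimnames = list(motion_outcomes(), motion_outcomes(),
                              c("Keep", "Break")))
  A1[, , 1] <- sharp
  A1[1, , 2] <- 1  # once sampling is broken, only Null is observed
  A2 <- array(0, c(2, 5, 2))
  A2[1, , 1] <- 1
  A2[2, , 2] <- 1  # unambiguous proprioception of the sampling state
  B1 <- array(diag(5), c(5, 5, 1))       # direction does not change
  B2 <- array(0, c(2, 2, 2))
  B2[, , 1] <- diag(2)                   # Keep: stay
  B2[2, , 2] <- 1                        # Break: absorbing sink
  C1 <- matrix(0, 5, T1)
  C2 <- rbind(Keep = rep(0, T1),
              Break = kappa * (seq_len(T1) - 1))
  D <- list(rep(1 / 5, 5), c(1, 0))
  policies <- rbind(Keep = c(1L, 1L), Break = c(1L, 2L))
  new_level_model(
    A = list(A1, A2), B = list(B1, B2), C = list(C1, C2), D = D,
    policies = policies, gamma = gamma, T = T1,
    modalities = c("motion", "sampling"),
    factors = c("direction", "sampling")
  )
}

#' Build the Level-2 (scene inference) generative model
#'
#' Level 2 models a whole trial at the timescale of saccades. Hidden factors:
#' the 48-dimensional scene x configuration state (constant within a trial)
#' and the eye position (9 locations, controllable). Modalities: the visual
#' stimulus at the fixated location (fed by Level-1 posteriors as inferred
#' observations), trial feedback (`NoFeedback, Correct, Incorrect`), and an
#' unambiguous proprioceptive eye-position report. All likelihoods are
#' deterministic; saccades are modeled as relocation transitions (each action
#' `u` moves the eyes to location `u` from anywhere). Preferences place
#' `pref_correct` nats on Correct and `pref_incorrect` nats on Incorrect
#' feedback, constant over time; other modalities carry flat preferences.
#'
#' @param prior_scene Optional scene type (index or label) whose prior
#'   probability is boosted; `NULL` gives the flat prior.
#' @param prior_strength Total prior mass on `prior_scene`, in `[0.25, 1]`.
#' @param T2 Trial horizon in saccades (default 10).
#' @param gamma Policy precision (default 512).
#' @param pref_correct,pref_incorrect Relative log-preferences (nats) for
#'   Correct and Incorrect feedback (defaults +2 and -4).
#' @return A `level_model` with 8 single-step policies (saccades to
#'   locations 2-9).
#' @export
build_level2_model <- function(prior_scene = NULL, prior_strength = 0.25,
                               T2 = 10, gamma = 512,
                               pref_correct = 2, pref_incorrect = -4) {
  ss <- enumerate_scene_states()
  A1 <- array(0, c(5, 48, 9))
  A2 <- array(0, c(3, 48, 9))
  A3 <- array(0, c(9, 48, 9))
  for (s in 1:48) {
    st <- ss[s, ]
    for (l in 1:9) {
      A1[stimulus_at(st, l), s, l] <- 1
      A2[feedback_at(st, l), s, l] <- 1
      A3[l, s, l] <- 1
    }
  }
  B1 <- array(diag(48), c(48, 48, 1))   # the scene does not change
  B2 <- array(0, c(9, 9, 9))
  for (u in 1:9) B2[u, , u] <- 1        # saccade: relocate to u from anywhere
  C1 <- matrix(0, 5, T2)
  C2 <- matrix(c(0, pref_correct, pref_incorrect), 3, T2)
  C3 <- matrix(0, 9, T2)
  D1 <- if (is.null(prior_scene)) rep(1 / 48, 48) else {
    set_scene_prior(prior_scene, prior_strength)
  }
  D <- list(D1, one_hot(1, 9))          # eyes start at the center
  policies <- cbind(rep(1L, 8), 2:9)
  new_level_model(
    A = list(A1, A2, A3), B = list(B1, B2), C = list(C1, C2, C3), D = D,
    policies = policies, gamma = gamma, T = T2,
    modalities = c("stimulus", "feedback", "proprioception"),
    factors = c("scene", "eye")
  )
}
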