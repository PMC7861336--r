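# The two-level scheduler: descending empirical priors over motion direction,
# the Level-1 sampling episode with its Keep/Break decision, ascending
# inferred observations, and the full trial loop.

#' Descending empirical prior over motion directions
#'
#' Passes the current Level-2 scene beliefs and the (post-saccade) eye
#' location through the Level-2 stimulus likelihood to obtain the predictive
#' distribution over `Null, UP, RIGHT, DOWN, LEFT` at the saccade target.
#' This distribution is installed as the Level-1 initial prior over motion
#' direction.
#'
#' @param scene_beliefs Probability vector over the 48 scene states.
#' @param location Saccade target location (1-9).
#' @param A21 The Level-2 stimulus likelihood array (5 x 48 x 9), e.g.
#'   `build_level2_model()$A[[1]]`.
#' @return Probability vector over the five motion outcomes.
#' @export
empirical_prior_down <- function(scene_beliefs, location, A21) {
  predictive_outcomes(A21, list(scene_beliefs, one_hot(location, 9)))
}

#' Wrap a Level-1 posterior as an inferred observation for Level 2
#'
#' The final Level-1 direction posterior is passed upward unchanged as a
#' graded ("soft") observation of the Level-2 stimulus modality.
#'
#' @param direction_posterior Probability vector over the five motion
#'   outcomes.
#' @return The same vector, flagged as inferred (attribute `inferred`).
#' @export
ascend_inferred_observation <- function(direction_posterior) {
  assert_prob(direction_posterior, arg = "direction_posterior")
  structure(direction_posterior, inferred = TRUE)
}

#' Run one Level-1 sampling episode (a single fixation)
#'
#' Loops for up to `model1$T` steps: a motion observation is sampled from the
#' generative process (the sharpened likelihood column of the true
#' direction), beliefs are updated for both the `Keep` and `Break` policies,
#' their variational and expected free energies are evaluated, and an action
#' is sampled from the policy posterior. The episode ends when `Break` is
#' sampled or the horizon is reached; `Break` is absorbing.
#'
#' @param model1 Level-1 model from [build_level1_model()].
#' @param true_direction Motion-outcome index (1-5) of the fixated stimulus.
#' @param D_empirical Empirical prior over motion directions from
#'   [empirical_prior_down()].
#' @param p_process Precision of the generative process (defaults to the
#'   model's own precision via the caller).
#' @param settings See [inference_settings()].
#' @param alpha Action precision passed to [select_action()] (default `Inf`,
#'   deterministic selection of the more probable policy).
#' @return List: `posterior` (final direction posterior), `break_time` (steps
#'   sampled, in `1..T1`), `policy_differential` (per-step
#'   `P(Keep) - P(Break)`, including the step at which the episode ended),
#'   `q_pi` (matrix of per-step policy posteriors).
#' @export
run_level1_episode <- function(model1, true_direction, D_empirical, p_process,
                               settings = inference_settings(), alpha = Inf) {
  assert_prob(D_empirical, arg = "D_empirical")
  model1$D[[1]] <- D_empirical
  observations <- list()
  past <- matrix(integer(0), 0, 2)
  differential <- numeric(0)
  q_pi <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("Keep", "Break")))
  for (t in seq_len(model1$T)) {
    o_motion <- one_hot(sample_motion(true_direction, p_process), 5)
    observations[[t]] <- list(o_motion, one_hot(1, 2))  # still Keep-sampling
    ev <- evaluate_policies(model1, observations, past, settings)
    differential[t] <- ev$q_pi[1] - ev$q_pi[2]
    q_pi <- rbind(q_pi, ev$q_pi)
    a <- select_action(ev$q_pi, alpha)
    if (a == 2L || t == model1$T) {
      post <- bayesian_model_average(
        lapply(ev$beliefs, function(b) b[[t]]), ev$q_pi)[[1]]
      return(list(posterior = post, break_time = t,
                  policy_differential = differential, q_pi = q_pi))
    }
    past <- rbind(past, model1$policies[1L, ])
  }
}

#' Run one full scene-construction trial
#'
#' The Level-2 loop: at each step the eight saccade policies are evaluated
#' (variational free energy of the observation history plus expected free
#' energy of the next observation), a saccade is sampled, and either (a) a
#' quadrant (locations 2-5) is fixated, triggering a Level-1 sampling episode
#' whose final direction posterior ascends as an inferred observation, or (b)
#' a choice location (6-9) is fixated, yielding feedback and terminating the
#' trial at its first categorization. Trials that never categorize within the
#' horizon are recorded as non-responding.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Optional integer seed for the trial's random stream.
#' @return Object of class `trial_record`: the true scene, per-step records
#'   (saccade, Level-1 break time, direction posterior, policy differentials),
#'   `latency` (Level-2 steps to first categorization, `NA` for
#'   non-responders), `choice`, `correct`, `responded`, and the trajectory of
#'   collapsed scene-type beliefs.
#' @export
run_trial <- function(config = default_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- merge_config(config)
  p_process <- if (is.null(cfg$p_process)) cfg$p_model else cfg$p_process
  model2 <- build_level2_model(cfg$prior_scene, cfg$prior_strength,
                               T2 = cfg$T2, gamma = cfg$gamma2,
                               pref_correct = cfg$pref_correct,
                               pref_incorrect = cfg$pref_incorrect)
  model1 <- build_level1_model(cfg$p_model, kappa = cfg$kappa,
                               T1 = cfg$T1, gamma = cfg$gamma1)
  settings <- inference_settings(cfg$max_iters, cfg$tol)
  scene <- sample_scene(cfg$true_scene)
  observations <- list(list(one_hot(1, 5), one_hot(1, 3), one_hot(1, 9)))
  past <- matrix(integer(0), 0, 2)
  steps <- list()
  scene_traj <- NULL
  latency <- NA_integer_
  choice <- NA_integer_
  correct <- NA
  feedback <- NA_integer_
  max_saccades <- min(cfg$T2, if (is.null(cfg$max_saccades)) cfg$T2 else cfg$max_saccades)
  for (k in seq_len(max_saccades)) {
    ev <- evaluate_policies(model2, observations, past, settings)
    bma <- bayesian_model_average(lapply(ev$beliefs, function(b) b[[k]]),
                                  ev$q_pi)
    scene_traj <- cbind(scene_traj, collapse_scene_beliefs(bma[[1]]))
    a <- select_action(ev$q_pi, cfg$alpha)
    target <- step_eyes(NA, model2$policies[a, 2L])
    if (target %in% 2:5) {
      d_emp <- empirical_prior_down(bma[[1]], target, model2$A[[1]])
      true_dir <- stimulus_at(scene, target)
      episode <- run_level1_episode(model1, true_dir, d_emp, p_process,
                                    settings, alpha = cfg$alpha)
      observations[[k + 1L]] <- list(
        ascend_inferred_observation(episode$posterior),
        one_hot(1, 3), one_hot(target, 9))
      steps[[k]] <- list(action = a, location = target,
                         break_time = episode$break_time,
                         direction_posterior = episode$posterior,
                         policy_differential = episode$policy_differential)
      past <- rbind(past, c(1L, target))
    } else {
      feedback <- feedback_at(scene, target)
      latency <- k
      choice <- target - 5L
      correct <- feedback == 2L
      observations[[k + 1L]] <- list(one_hot(1, 5), one_hot(feedback, 3),
                                     one_hot(target, 9))
      steps[[k]] <- list(action = a, location = target, break_time = NA,
                         direction_posterior = NULL,
                         policy_differential = NULL)
      break
    }
  }
  structure(list(
    scene = scene, steps = steps,
    latency = latency, choice = choice, correct = correct,
    feedback = feedback, responded = !is.na(latency),
    scene_beliefs = scene_traj, config = cfg
  ), class = "trial_record")
}

# Collapse the 48-state belief to the four scene types by summing each
# 12-configuration block.
collapse_scene_beliefs <- function(q48) {
  vapply(1:4, function(sc) sum(q48[(sc - 1L) * 12L + 1:12]), numeric(1))
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record>\n")
  cat("  true scene:", x$scene$scene_type,
      sprintf("(RDMs in quadrants %d and %d)\n", x$scene$q1, x$scene$q2))
  locs <- vapply(x$steps, function(s) s$location, numeric(1))
  cat("  saccades:  ", paste(locs, collapse = " -> "), "\n")
  if (x$responded) {
    cat(sprintf("  categorized as %s at step %d: %s\n",
                scene_types()[x$choice], x$latency,
                feedback_outcomes()[x$feedback]))
  } else {
    cat("  non-responding (no categorization within the horizon)\n")
  }
  invisible(x)
}
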