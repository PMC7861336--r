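# The generative process: the "real" world the agent acts in. It shares the
# constructors of the generative model (same scene enumeration, same sharpened
# motion likelihood), so that setting the process precision equal to the model
# precision reproduces the matched model/process setting used throughout.

#' Sample a scene (with configuration) for a trial
#'
#' @param forced_scene Optional scene type (index or label); restricts
#'   sampling to that scene's 12 configurations. `NULL` samples uniformly over
#'   all 48 states.
#' @return One row of [enumerate_scene_states()].
#' @export
sample_scene <- function(forced_scene = NULL) {
  ss <- enumerate_scene_states()
  if (is.null(forced_scene)) {
    ss[sample.int(48, 1), ]
  } else {
    if (is.character(forced_scene)) forced_scene <- match(forced_scene, scene_types())
    if (is.na(forced_scene) || !forced_scene %in% 1:4) {
      stop("'forced_scene' must identify one of the four scene types",
           call. = FALSE)
    }
    block <- (forced_scene - 1L) * 12L + 1:12
    ss[block[sample.int(12, 1)], ]
  }
}

#' Sample a stochastic motion observation
#'
#' Draws one observation from the sharpened likelihood column of the true
#' direction: the true direction is observed with probability
#' `exp(p) / (exp(p) + 3)`, each other direction with the complementary mass
#' split evenly. The `Null` state always yields `Null`.
#'
#' @param true_direction Motion-outcome index 1-5 (1 = `Null`).
#' @param p_process Positive precision of the generative process.
#' @return Motion-outcome index 1-5.
#' @export
sample_motion <- function(true_direction, p_process) {
  if (!is.numeric(true_direction) || length(true_direction) != 1 ||
      !true_direction %in% 1:5) {
    stop("'true_direction' must be an outcome index in 1..5", call. = FALSE)
  }
  col <- sharpen_likelihood(diag(5), p_process)[, true_direction]
  sample.int(5, 1, prob = col)
}

#' Deterministic eye-movement transition
#'
#' Saccades relocate the eyes to the action's target location from anywhere
#' (the transition matrix for action `u` has a row of ones on row `u`).
#'
#' @param current Current location 1-9 (unused by the deterministic dynamics,
#'   kept for interface symmetry).
#' @param action Saccade target, an integer in 2..9.
#' @return The new location (`action`).
#' @export
step_eyes <- function(current, action) {
  if (!is.numeric(action) || length(action) != 1 ||
      !(action %in% 2:9)) {
    stop("'action' must be a saccade target in 2..9", call. = FALSE)
  }
  as.integer(action)
}
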