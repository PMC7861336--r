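# State space of the scene-construction task: 4 scene types x 12 ordered
# placements of two RDM patches in four quadrants = 48 joint states.

#' Outcome, scene and location codings
#'
#' Fixed labels used throughout the package. Outcomes of the motion modality
#' are `Null, UP, RIGHT, DOWN, LEFT` (Null first, always observed
#' unambiguously). Scene types are named by the two perpendicular motion
#' directions of their constituent RDMs. Locations: 1 is the central start
#' position, 2-5 the four quadrants (upper-left, upper-right, lower-left,
#' lower-right), 6-9 the four choice locations mapped in order to the scene
#' types (a saccade to location 6 reports UP-RIGHT, 7 RIGHT-DOWN, 8 DOWN-LEFT,
#' 9 LEFT-UP).
#'
#' @name codings
#' @keywords internal
NULL

motion_outcomes <- function() c("Null", "UP", "RIGHT", "DOWN", "LEFT")
scene_types <- function() c("UP-RIGHT", "RIGHT-DOWN", "DOWN-LEFT", "LEFT-UP")
feedback_outcomes <- function() c("NoFeedback", "Correct", "Incorrect")

# Motion-outcome indices (into motion_outcomes()) of the first and second RDM
# of each scene type.
scene_directions <- function() {
  matrix(c(2, 3,   # UP-RIGHT
           3, 4,   # RIGHT-DOWN
           4, 5,   # DOWN-LEFT
           5, 2),  # LEFT-UP
         ncol = 2, byrow = TRUE,
         dimnames = list(scene_types(), c("first", "second")))
}

#' Enumerate the 48 scene x configuration hidden states
#'
#' Deterministic ordering: scene types in the order UP-RIGHT, RIGHT-DOWN,
#' DOWN-LEFT, LEFT-UP; within each scene, the 12 ordered pairs of distinct
#' quadrants (quadrant of the first RDM, quadrant of the second RDM) in
#' lexicographic order. The ordering is frozen so that state indices are
#' reproducible across runs; each scene occupies a contiguous block of 12
#' states (UP-RIGHT: 1-12, RIGHT-DOWN: 13-24, DOWN-LEFT: 25-36, LEFT-UP:
#' 37-48).
#'
#' @return Data frame with one row per hidden state: `index` (1-48), `scene`
#'   (integer 1-4), `scene_type` (label), `q1`, `q2` (quadrants 1-4 of the
#'   first and second RDM).
#' @export
#' @examples
#' ss <- enumerate_scene_states()
#' nrow(ss)           # 48
#' table(ss$scene)    # 12 configurations per scene
.scene_cache <- new.env(parent = emptyenv())

enumerate_scene_states <- function() {
  if (!is.null(.scene_cache$states)) return(.scene_cache$states)
  pairs <- expand.grid(q2 = 1:4, q1 = 1:4)[, c("q1", "q2")]
  pairs <- pairs[pairs$q1 != pairs$q2, ]
  pairs <- pairs[order(pairs$q1, pairs$q2), ]
  out <- do.call(rbind, lapply(1:4, function(sc) {
    data.frame(scene = sc, scene_type = scene_types()[sc],
               q1 = pairs$q1, q2 = pairs$q2)
  }))
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  .scene_cache$states <- out
  out
}

#' Stimulus visible at a fixation location for a given hidden state
#'
#' @param state One row of [enumerate_scene_states()] (or a list with fields
#'   `scene`, `q1`, `q2`).
#' @param location Integer 1-9.
#' @return Motion-outcome index: the direction of the RDM occupying the
#'   fixated quadrant, or 1 (`Null`) when the location is the start position,
#'   an empty quadrant, or a choice location.
#' @export
stimulus_at <- function(state, location) {
  if (!is.numeric(location) || length(location) != 1 ||
      location < 1 || location > 9 || location != round(location)) {
    stop("'location' must be an integer in 1..9", call. = FALSE)
  }
  if (location < 2 || location > 5) return(1L)
  quad <- location - 1L
  dirs <- scene_directions()[state$scene, ]
  if (quad == state$q1) return(as.integer(dirs[1]))
  if (quad == state$q2) return(as.integer(dirs[2]))
  1L
}

#' Feedback received at a location for a given hidden state
#'
#' @inheritParams stimulus_at
#' @return Feedback-outcome index: 1 (`NoFeedback`) at locations 1-5;
#'   2 (`Correct`) iff `location - 5` matches the state's scene type,
#'   3 (`Incorrect`) otherwise.
#' @export
feedback_at <- function(state, location) {
  if (!is.numeric(location) || length(location) != 1 ||
      location < 1 || location > 9 || location != round(location)) {
    stop("'location' must be an integer in 1..9", call. = FALSE)
  }
  if (location <= 5) return(1L)
  if (location - 5L == state$scene) 2L else 3L
}

#' Prior over the 48 scene states concentrated on one scene type
#'
#' The target scene's 12 configurations share probability mass `strength`
#' uniformly; each other scene's 12 configurations share `(1 - strength) / 3`
#' uniformly. `strength = 0.25` is the flat prior; `strength = 1` puts all
#' mass on the target scene.
#'
#' @param scene Scene-type index 1-4 (or label from [scene_types()]).
#' @param strength Total prior mass on the target scene, in `[0.25, 1]`
#'   (below 0.25 the target would be less likely than the alternatives, which
#'   is outside the intended manipulation).
#' @return Probability vector of length 48.
#' @export
#' @examples
#' d <- set_scene_prior(2, 0.5)
#' sum(d[13:24])  # 0.5 on RIGHT-DOWN
set_scene_prior <- function(scene, strength) {
  if (is.character(scene)) scene <- match(scene, scene_types())
  if (is.na(scene) || !scene %in% 1:4) {
    stop("'scene' must identify one of the four scene types", call. = FALSE)
  }
  if (!is.numeric(strength) || length(strength) != 1 ||
      strength < 0.25 || strength > 1) {
    stop("'strength' must lie in [0.25, 1]", call. = FALSE)
  }
  d <- rep((1 - strength) / 3 / 12, 48)
  d[(scene - 1L) * 12L + 1:12] <- strength / 12
  norm_vec(d)
}
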