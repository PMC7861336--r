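# Flat key-value configuration for task, agent, and experiment parameters.

#' Default configuration
#'
#' Flat list of the parameters that define a simulated agent and task:
#' \describe{
#'   \item{p_model}{Sensory precision of the agent's Level-1 likelihood.}
#'   \item{p_process}{Precision of the generative process; `NULL` means equal
#'     to `p_model` (the matched setting used throughout).}
#'   \item{kappa}{Urgency slope of the Break-sampling preference, nats/step.}
#'   \item{T1, T2}{Level-1 and Level-2 horizons (time steps).}
#'   \item{gamma1, gamma2}{Policy precisions at the two levels.}
#'   \item{pref_correct, pref_incorrect}{Feedback log-preferences (nats).}
#'   \item{prior_scene, prior_strength}{Optional boosted scene type and its
#'     total prior mass (`NULL` / 0.25 gives the flat prior).}
#'   \item{true_scene}{Optional forced true scene for the environment.}
#'   \item{alpha}{Action precision for [select_action()]; default `Inf`
#'     (deterministic selection with randomized ties), `NULL` for categorical
#'     sampling.}
#'   \item{max_iters, tol}{Fixed-point iteration settings.}
#'   \item{max_saccades}{Optional cap on Level-2 steps (used by the dwell
#'     analysis, which only needs the first fixation).}
#'   \item{seed}{Master seed for experiment drivers.}
#' }
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    p_model = 2,
    p_process = NULL,
    kappa = 0.005,
    T1 = 20,
    T2 = 10,
    gamma1 = 512,
    gamma2 = 512,
    pref_correct = 2,
    pref_incorrect = -4,
    prior_scene = NULL,
    prior_strength = 0.25,
    true_scene = NULL,
    alpha = Inf,
    max_iters = 16,
    tol = 1e-4,
    max_saccades = NULL,
    seed = 1
  )
}

merge_config <- function(config) {
  cfg <- default_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

#' Read a configuration file
#'
#' Accepts a flat key-value file in YAML (`.yml`/`.yaml`) or JSON (`.json`);
#' keys missing from the file take their [default_config()] values.
#'
#' @param path Path to the configuration file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config file must be .yaml/.yml or .json", call. = FALSE)
  )
  unknown <- setdiff(names(raw), names(default_config()))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  merge_config(raw)
}
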