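# Batch simulation drivers: precision sweep (latency/accuracy vs sensory
# precision), prior-strength sweep, and the fixational dwell-time analysis
# (first-saccade break times and Keep/Break policy differentials).

#' Default sensory-precision grid
#'
#' Twelve values log-spaced on `[0.1, 10]`.
#'
#' @param n Number of grid points.
#' @param lo,hi Grid end points.
#' @return Numeric vector.
#' @export
default_p_levels <- function(n = 12, lo = 0.1, hi = 10) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Default prior-strength grid
#'
#' @return `c(0.25, 0.4, 0.5, 0.6, 0.75, 0.9)`.
#' @export
default_prior_strengths <- function() c(0.25, 0.4, 0.5, 0.6, 0.75, 0.9)

# Independent per-trial seeds derived from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Summarize a group of trials into one result row
#'
#' Latency is averaged over responding trials; accuracy is
#' `100 * correct / responding`; break time and policy differentials are
#' taken from the first saccade's Level-1 episode only.
#'
#' @param trials List of `trial_record` objects from one homogeneous
#'   condition.
#' @param n_diff_steps Number of Level-1 steps over which mean pre-break
#'   policy differentials are reported (default 10).
#' @return One-row data frame, or `NULL` (with a warning) when no trial in
#'   the group responded.
#' @export
summarize_trials <- function(trials, n_diff_steps = 10) {
  responded <- vapply(trials, function(tr) isTRUE(tr$responded), logical(1))
  if (!any(responded)) {
    warning("group contains no responding trials; row omitted", call. = FALSE)
    return(NULL)
  }
  resp <- trials[responded]
  latency <- vapply(resp, function(tr) tr$latency, numeric(1))
  correct <- vapply(resp, function(tr) isTRUE(tr$correct), logical(1))
  first <- lapply(trials, first_fixation)
  bt <- vapply(first, function(s) if (is.null(s)) NA_real_ else s$break_time,
               numeric(1))
  diffs <- matrix(NA_real_, length(trials), n_diff_steps)
  for (i in seq_along(first)) {
    s <- first[[i]]
    if (is.null(s)) next
    pre <- utils::head(s$policy_differential, s$break_time - 1L)
    take <- min(length(pre), n_diff_steps)
    if (take > 0) diffs[i, seq_len(take)] <- pre[seq_len(take)]
  }
  row <- data.frame(
    n_trials = length(trials),
    n_responding = sum(responded),
    mean_latency = mean(latency),
    accuracy = 100 * mean(correct),
    mean_break_time = mean(bt, na.rm = TRUE)
  )
  md <- colMeans(diffs, na.rm = TRUE)
  md[is.nan(md)] <- NA_real_
  for (j in seq_len(n_diff_steps)) row[[paste0("diff_step", j)]] <- md[j]
  row
}

# First quadrant fixation of a trial (NULL if the first action categorized).
first_fixation <- function(tr) {
  if (length(tr$steps) == 0) return(NULL)
  s <- tr$steps[[1]]
  if (is.na(s$break_time)) NULL else s
}

run_condition <- function(config, n_trials, seeds, keep_trials = FALSE) {
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- config
    if (isTRUE(cfg$incorrect_prior)) {
      cfg$incorrect_prior <- NULL
      set.seed(seeds[i])
      true_scene <- sample.int(4, 1)
      cfg$true_scene <- true_scene
      cfg$prior_scene <- sample(setdiff(1:4, true_scene), 1)
    } else if (isTRUE(cfg$random_prior_scene)) {
      cfg$random_prior_scene <- NULL
      set.seed(seeds[i])
      cfg$prior_scene <- sample.int(4, 1)
    }
    trials[[i]] <- run_trial(cfg, seed = seeds[i])
  }
  trials
}

#' Sweep sensory precision under flat scene priors
#'
#' For each precision level, simulates independent trials with scenes and
#' configurations sampled uniformly, and reports mean categorization latency,
#' accuracy, and first-saccade break time.
#'
#' @param p_levels Precision grid (default [default_p_levels()]).
#' @param n_trials Trials per level (default 185).
#' @param seed Master seed.
#' @param config Base configuration overrides.
#' @param keep_trials Attach the raw `trial_record`s as attribute `trials`.
#' @return A `sweep_result` data frame, one row per precision level.
#' @export
run_precision_sweep <- function(p_levels = default_p_levels(),
                                n_trials = 185, seed = 1,
                                config = list(), keep_trials = FALSE) {
  rows <- list()
  all_trials <- list()
  for (j in seq_along(p_levels)) {
    cfg <- merge_config(config)
    cfg$p_model <- p_levels[j]
    seeds <- derive_seeds(seed + j, n_trials)
    trials <- run_condition(cfg, n_trials, seeds)
    row <- summarize_trials(trials)
    if (is.null(row)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(p = p_levels[j], prior_strength = cfg$prior_strength), row)
    if (keep_trials) all_trials <- c(all_trials, trials)
  }
  as_sweep_result(rows, if (keep_trials) all_trials else NULL)
}

#' Sweep prior-belief strength against sensory precision
#'
#' For each (strength, precision) pair, simulates trials in which the agent
#' holds a prior of the given strength on one scene type. With
#' `incorrect_prior = TRUE` (the default) the prior's scene is drawn
#' uniformly from the three scene types other than the true scene, so the
#' strongest priors drive accuracy toward 0 rather than chance.
#'
#' @param strengths Prior-strength grid (default
#'   [default_prior_strengths()]).
#' @param p_levels Precision grid.
#' @param n_trials Trials per condition.
#' @param seed Master seed.
#' @param incorrect_prior Draw the prior scene from the non-true scenes.
#' @param config Base configuration overrides.
#' @param keep_trials Attach raw trials as attribute `trials`.
#' @return A `sweep_result` data frame, one row per (strength, precision).
#' @export
run_prior_sweep <- function(strengths = default_prior_strengths(),
                            p_levels = default_p_levels(),
                            n_trials = 185, seed = 1,
                            incorrect_prior = TRUE,
                            config = list(), keep_trials = FALSE) {
  rows <- list()
  all_trials <- list()
  for (s in seq_along(strengths)) {
    for (j in seq_along(p_levels)) {
      cfg <- merge_config(config)
      cfg$p_model <- p_levels[j]
      cfg$prior_strength <- strengths[s]
      if (strengths[s] > 0.25) {
        if (incorrect_prior) cfg$incorrect_prior <- TRUE else {
          cfg$random_prior_scene <- TRUE
        }
      }
      seeds <- derive_seeds(seed + j, n_trials)
      trials <- run_condition(cfg, n_trials, seeds)
      row <- summarize_trials(trials)
      if (is.null(row)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(p = p_levels[j], prior_strength = strengths[s]), row)
      if (keep_trials) all_trials <- c(all_trials, trials)
    }
  }
  as_sweep_result(rows, if (keep_trials) all_trials else NULL)
}

#' Fixational dwell-time analysis
#'
#' For each (precision, strength) condition, simulates trials whose prior is
#' concentrated on a randomly drawn scene type and records the first
#' saccade's Level-1 break time and the pre-break Keep/Break policy
#' differentials over the first 10 sampling steps. Only the first fixation is
#' simulated (the trial is stopped after it), since the analysis uses nothing
#' else.
#'
#' @param p_levels Precision grid.
#' @param strengths Prior strengths (default `c(0.5, 0.75)`).
#' @param n_trials Trials per condition (default 250).
#' @param seed Master seed.
#' @param config Base configuration overrides.
#' @return A `sweep_result` data frame with one row per condition; attribute
#'   `differentials` holds the per-precision mean pre-break differential for
#'   Level-1 steps 1-10, averaged across prior strengths.
#' @export
run_dwell_analysis <- function(p_levels = default_p_levels(),
                               strengths = c(0.5, 0.75),
                               n_trials = 250, seed = 1,
                               config = list()) {
  rows <- list()
  for (s in seq_along(strengths)) {
    for (j in seq_along(p_levels)) {
      cfg <- merge_config(config)
      cfg$p_model <- p_levels[j]
      cfg$prior_strength <- strengths[s]
      cfg$random_prior_scene <- strengths[s] > 0.25
      cfg$max_saccades <- 1L
      seeds <- derive_seeds(seed + 1000L * s + j, n_trials)
      trials <- run_condition(cfg, n_trials, seeds)
      has_fix <- !vapply(trials, function(tr) is.null(first_fixation(tr)),
                         logical(1))
      if (!any(has_fix)) next
      first <- lapply(trials[has_fix], function(tr) tr$steps[[1]])
      bt <- vapply(first, function(x) x$break_time, numeric(1))
      diffs <- matrix(NA_real_, length(first), 10)
      for (i in seq_along(first)) {
        pre <- utils::head(first[[i]]$policy_differential,
                           first[[i]]$break_time - 1L)
        take <- min(length(pre), 10L)
        if (take > 0) diffs[i, seq_len(take)] <- pre[seq_len(take)]
      }
      row <- data.frame(
        p = p_levels[j], prior_strength = strengths[s],
        n_trials = n_trials, n_responding = NA_real_,
        mean_latency = NA_real_, accuracy = NA_real_,
        mean_break_time = mean(bt),
        max_break_time = max(bt),
        min_pre_break_differential = suppressWarnings(min(diffs, na.rm = TRUE))
      )
      md <- colMeans(diffs, na.rm = TRUE)
      md[is.nan(md)] <- NA_real_
      for (q in 1:10) row[[paste0("diff_step", q)]] <- md[q]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- as_sweep_result(rows, NULL)
  diff_cols <- paste0("diff_step", 1:10)
  agg <- stats::aggregate(out[diff_cols], by = list(p = out$p),
                          FUN = mean, na.rm = TRUE)
  attr(out, "differentials") <- agg
  out
}

#' Accuracy of a uniform-random categorizer
#'
#' The chance-ablation agent guesses one of the four choice locations
#' uniformly at the first step of every trial; its long-run accuracy is the
#' 25% chance baseline.
#'
#' @param n_trials Number of simulated guesses.
#' @param seed Seed.
#' @return Accuracy in percent.
#' @export
chance_accuracy <- function(n_trials = 1e4, seed = 1) {
  set.seed(seed)
  correct <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    scene <- sample_scene()
    guess_location <- sample(6:9, 1)
    correct[i] <- feedback_at(scene, guess_location) == 2L
  }
  100 * mean(correct)
}

as_sweep_result <- function(rows, trials) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  if (!is.null(trials)) attr(out, "trials") <- trials
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", nrow(x), " condition(s)\n", sep = "")
  cols <- intersect(c("p", "prior_strength", "n_trials", "n_responding",
                      "mean_latency", "accuracy", "mean_break_time"),
                    names(x))
  print.data.frame(format(as.data.frame(x)[cols], digits = 3), ...)
  invisible(x)
}

#' Plot a sweep result
#'
#' Line plots of accuracy and mean latency (or mean break time for dwell
#' analyses) against log sensory precision, one line per prior strength.
#'
#' @param x A `sweep_result`.
#' @param which `"performance"` (latency + accuracy) or `"dwell"` (break
#'   time).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, which = c("performance", "dwell"), ...) {
  which <- match.arg(which)
  strengths <- sort(unique(x$prior_strength))
  wide <- function(col) {
    vapply(strengths, function(s) {
      y <- x[x$prior_strength == s, ]
      y[[col]][match(sort(unique(x$p)), y$p)]
    }, numeric(length(unique(x$p))))
  }
  p <- sort(unique(x$p))
  if (which == "performance") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    graphics::matplot(p, wide("mean_latency"), type = "b", log = "x",
                      xlab = "sensory precision p", ylab = "mean latency (steps)",
                      pch = 16, lty = 1, ...)
    graphics::matplot(p, wide("accuracy"), type = "b", log = "x",
                      xlab = "sensory precision p", ylab = "accuracy (%)",
                      pch = 16, lty = 1, ...)
  } else {
    graphics::matplot(p, wide("mean_break_time"), type = "b", log = "x",
                      xlab = "sensory precision p",
                      ylab = "mean first-saccade break time (steps)",
                      pch = 16, lty = 1, ...)
  }
  invisible(x)
}
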