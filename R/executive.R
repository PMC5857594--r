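# Conflict-task (numerical Stroop, Simon, Flanker) reaction-time scoring.
# Trials are one participant x one task: columns `condition` (congruent,
# neutral, incongruent), `rt_ms` (> 0) and `correct` (logical/0-1); an optional
# `task` column is carried through.

CONDITIONS <- c("congruent", "neutral", "incongruent")

check_rt_trials <- function(trials) {
  if (!is.data.frame(trials) || !all(c("condition", "rt_ms", "correct") %in% names(trials)))
    abort("trials needs columns condition, rt_ms, correct", "adaptaaf_invalid_config")
  if (!all(trials$condition %in% CONDITIONS))
    abort("condition must be one of congruent, neutral, incongruent", "adaptaaf_invalid_config")
  if (anyNA(trials$rt_ms) || any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0))
    abort("rt_ms must be finite and positive", "adaptaaf_invalid_config")
  invisible(trials)
}

#' Trim error and outlier trials from a conflict task
#'
#' Incorrect responses are removed first; then, per condition, correct trials
#' whose reaction time lies more than `sd_bound` standard deviations from that
#' condition's mean (mean and SD computed on the correct trials) are removed.
#' Trimming is single-pass: bounds are not recomputed after removal. With zero
#' within-condition spread nothing is removed (deviations of 0 are within any
#' bound).
#'
#' @param trials One participant's trials for one task.
#' @param sd_bound Outlier bound in within-condition standard deviations
#'   (default 2.5).
#' @return List: `trials` (the retained trials), `fraction_removed_errors` and
#'   `fraction_removed_outliers` (both relative to the input trial count).
#' @export
trim_trials <- function(trials, sd_bound = 2.5) {
  check_rt_trials(trials)
  if (!is_number(sd_bound) || sd_bound <= 0)
    abort("sd_bound must be positive", "adaptaaf_invalid_config")
  n0 <- nrow(trials)
  ok <- as.logical(trials$correct)
  correct <- trials[ok, , drop = FALSE]
  n_err <- n0 - nrow(correct)

  keep <- rep(TRUE, nrow(correct))
  present <- intersect(CONDITIONS, unique(trials$condition))
  for (cond in present) {
    sel <- correct$condition == cond
    if (sum(sel) < 2L)
      abort(sprintf("condition '%s' has fewer than 2 correct trials", cond),
            "adaptaaf_insufficient_data")
    m <- mean(correct$rt_ms[sel])
    s <- stats::sd(correct$rt_ms[sel])
    keep[sel] <- abs(correct$rt_ms[sel] - m) <= sd_bound * s
  }
  kept <- correct[keep, , drop = FALSE]
  for (cond in present) {
    if (sum(kept$condition == cond) < 2L)
      abort(sprintf("condition '%s' has fewer than 2 trials after trimming", cond),
            "adaptaaf_insufficient_data")
  }
  rownames(kept) <- NULL
  list(trials = kept,
       fraction_removed_errors = n_err / n0,
       fraction_removed_outliers = sum(!keep) / n0)
}

#' Interference, congruency, and incongruity effects
#'
#' From trimmed trials with all three conditions present:
#' * interference = mean RT(congruent) - mean RT(incongruent) — negative when
#'   incongruent trials are slower, the usual direction;
#' * congruency = mean RT(neutral) - mean RT(congruent);
#' * incongruity = mean RT(incongruent) - mean RT(neutral).
#'
#' The three effects sum to zero by construction.
#'
#' @param trials Trimmed trials (see [trim_trials()]).
#' @return One-row data frame: `interference_ms`, `congruency_ms`,
#'   `incongruity_ms`.
#' @export
conflict_scores <- function(trials) {
  check_rt_trials(trials)
  if (!all(CONDITIONS %in% trials$condition))
    abort("all three conditions (congruent, neutral, incongruent) are required",
          "adaptaaf_insufficient_data")
  m <- vapply(CONDITIONS, function(cond)
    mean(trials$rt_ms[trials$condition == cond]), numeric(1L))
  data.frame(interference_ms = m[["congruent"]] - m[["incongruent"]],
             congruency_ms = m[["neutral"]] - m[["congruent"]],
             incongruity_ms = m[["incongruent"]] - m[["neutral"]])
}

#' Trim and score a conflict task in one step
#'
#' @param trials One participant's raw trials for one task.
#' @param sd_bound Outlier bound passed to [trim_trials()].
#' @return One-row data frame: the three effects plus the removal fractions.
#' @export
score_conflict_task <- function(trials, sd_bound = 2.5) {
  trimmed <- trim_trials(trials, sd_bound)
  out <- conflict_scores(trimmed$trials)
  out$fraction_removed_errors <- trimmed$fraction_removed_errors
  out$fraction_removed_outliers <- trimmed$fraction_removed_outliers
  out
}
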