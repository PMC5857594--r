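# Fixture builders shared across test files.

# Noiseless track for a speaker who compensates a constant fraction `rho` of
# the inverse alteration from `onset` onward (baseline production before).
# The default onset sits two trials past the baseline window so the smoothing
# neighbourhood of baseline trials never touches the compensation step.
constant_compensation_track <- function(rho, baseline_f1 = 500, baseline_f2 = 1800,
                                        n_trials = 100, onset = 23) {
  f1 <- rep(baseline_f1, n_trials)
  f2 <- rep(baseline_f2, n_trials)
  late <- onset:n_trials
  f1[late] <- baseline_f1 + rho * 150
  f2[late] <- baseline_f2 - rho * 300
  data.frame(participant = "P1", trial = seq_len(n_trials), f1 = f1, f2 = f2)
}

# Compensation series with prescribed values on the hold and end windows.
fixed_series <- function(hold_value, end_value, baseline_value = 0) {
  cs <- data.frame(trial = 1:100,
                   c = c(rep(baseline_value, 60), rep(hold_value, 20), rep(end_value, 20)))
  attr(cs, "baseline_f1") <- 500
  attr(cs, "baseline_f2") <- 1800
  attr(cs, "magnitude") <- alteration_magnitude(c(-150, 300))
  class(cs) <- c("compensation_series", "data.frame")
  cs
}

# Balanced conflict-task table with explicit per-condition reaction times.
rt_table <- function(congruent, neutral, incongruent, correct = TRUE) {
  n <- c(length(congruent), length(neutral), length(incongruent))
  data.frame(condition = rep(c("congruent", "neutral", "incongruent"), n),
             rt_ms = c(congruent, neutral, incongruent),
             correct = correct)
}

# A deterministic step observer: p = 1 above threshold, 0 below (no guessing;
# the logistic transition band is narrower than any difference the staircase
# can visit).
step_observer <- function(threshold)
  observer_params(threshold, slope = 1e-12, guess = 0)
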