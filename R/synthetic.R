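# Synthetic-data generators: adapting speakers, psychometric observers,
# conflict-task reaction-time tables, melody stimulus pairs, and linked
# multi-task cohorts with recorded ground truth. These emulate the study
# conditions (100-trial /pep/ sessions against the (-150, +300) Hz alteration,
# 2AFC discrimination observers, 48-trial conflict tasks, major-scale melody
# pairs) so the whole analysis pipeline can be exercised and validated without
# raw recordings.

#' Simulated speaker parameters
#'
#' The speaker model is an error-corrective update with a feedforward anchor
#' and an acuity-scaled dead zone. The compensation state `p` (a 2-vector of
#' Hz offsets applied to baseline F1/F2) evolves per trial as
#' `p <- p + gain * e - anchor * p`, where the perceived error
#' `e = -(shift + p)` whenever the perceived deviation `|shift + p|` exceeds
#' `dead_zone_hz`, else 0. The anchor pulls production back toward the
#' feedforward target, so steady-state compensation is the partial fraction
#' `gain / (gain + anchor)` of the full inverse alteration — mirroring the
#' incomplete (~20-40%) adaptation seen empirically. The dead zone implements
#' the auditory target region: speakers with higher acuity tolerate smaller
#' feedback deviations, hence `dead_zone_hz = dead_zone_scale * (1 - acuity)`.
#'
#' @param baseline_f1,baseline_f2 Habitual vowel formants, Hz (defaults
#'   500/1800, a mid-front vowel).
#' @param acuity Auditory acuity in (0, 1]; drives the defaults of `gain` and
#'   `dead_zone_hz`.
#' @param gain Per-trial corrective learning rate (default
#'   `0.02 + 0.12 * acuity`).
#' @param anchor Feedforward pull toward the unadapted target (default 0.2).
#' @param dead_zone_hz Feedback deviation below which no correction occurs
#'   (default `dead_zone_scale * (1 - acuity)`).
#' @param dead_zone_scale Dead-zone magnitude for a hypothetical zero-acuity
#'   speaker, Hz (default 120).
#' @param noise_sd Trial-to-trial production noise per formant, Hz (default
#'   10).
#' @param failure_rate Probability that a trial's formant track is missing
#'   (default 0.01, matching the ~1% observed tracking failure rate).
#' @return List of class `speaker_params`.
#' @export
speaker_params <- function(baseline_f1 = 500, baseline_f2 = 1800,
                           acuity = 0.5, gain = NULL, anchor = 0.2,
                           dead_zone_hz = NULL, dead_zone_scale = 120,
                           noise_sd = 10, failure_rate = 0.01) {
  if (!is_number(acuity) || acuity <= 0 || acuity > 1)
    abort("acuity must be in (0, 1]", "adaptaaf_invalid_config")
  gain <- gain %||% (0.02 + 0.12 * acuity)
  dead_zone_hz <- dead_zone_hz %||% (dead_zone_scale * (1 - acuity))
  if (!is_number(baseline_f1) || baseline_f1 <= 0 ||
      !is_number(baseline_f2) || baseline_f2 <= 0)
    abort("baseline formants must be positive", "adaptaaf_invalid_config")
  if (!is_number(gain) || gain < 0 || !is_number(anchor) || anchor < 0)
    abort("gain and anchor must be non-negative", "adaptaaf_invalid_config")
  if (!is_number(dead_zone_hz) || dead_zone_hz < 0)
    abort("dead_zone_hz must be non-negative", "adaptaaf_invalid_config")
  if (!is_number(noise_sd) || noise_sd < 0)
    abort("noise_sd must be non-negative", "adaptaaf_invalid_config")
  if (!is_number(failure_rate) || failure_rate < 0 || failure_rate > 1)
    abort("failure_rate must be in [0, 1]", "adaptaaf_invalid_config")
  if (gain + anchor >= 1)
    abort("gain + anchor must be < 1 (update would diverge)", "adaptaaf_divergent_speaker")
  structure(list(baseline_f1 = baseline_f1, baseline_f2 = baseline_f2,
                 acuity = acuity, gain = gain, anchor = anchor,
                 dead_zone_hz = dead_zone_hz, noise_sd = noise_sd,
                 failure_rate = failure_rate),
            class = "speaker_params")
}

#' Simulate a speaker's formant track under a perturbation schedule
#'
#' Runs the error-corrective speaker model (see [speaker_params()]) over the
#' schedule. Emitted formants are `baseline + p + Gaussian noise`; each trial
#' is independently missing with the speaker's `failure_rate`. With no noise,
#' no dead zone, and anchor 0 the hold-phase compensation converges to the full
#' inverse alteration; with an anchor the fixed point is
#' `gain / (gain + anchor)` of it.
#'
#' @param params A [speaker_params()].
#' @param schedule A [build_schedule()] result.
#' @param seed Optional integer seed.
#' @return Formant track data frame (`trial`, `f1`, `f2`, NA on failed trials)
#'   with attribute `compensation`: the n x 2 matrix of latent compensation
#'   states.
#' @export
simulate_speaker <- function(params, schedule, seed = NULL) {
  if (!inherits(params, "speaker_params"))
    abort("params must be speaker_params", "adaptaaf_invalid_config")
  if (!inherits(schedule, "perturbation_schedule"))
    abort("schedule must be a perturbation_schedule", "adaptaaf_invalid_config")
  if (params$gain + params$anchor >= 1)
    abort("gain + anchor must be < 1 (update would diverge)", "adaptaaf_divergent_speaker")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  shifts <- cbind(schedule$f1_shift, schedule$f2_shift)
  p <- c(0, 0)
  P <- matrix(0, n, 2L)
  for (t in seq_len(n)) {
    P[t, ] <- p
    fb <- shifts[t, ] + p
    e <- if (sqrt(sum(fb^2)) > params$dead_zone_hz) -fb else c(0, 0)
    p <- p + params$gain * e - params$anchor * p
  }
  noise <- matrix(stats::rnorm(2L * n, 0, params$noise_sd), n, 2L)
  f1 <- params$baseline_f1 + P[, 1L] + noise[, 1L]
  f2 <- params$baseline_f2 + P[, 2L] + noise[, 2L]
  miss <- stats::runif(n) < params$failure_rate
  f1[miss] <- NA_real_
  f2[miss] <- NA_real_
  out <- data.frame(trial = schedule$trial, f1 = f1, f2 = f2)
  attr(out, "compensation") <- P
  attr(out, "params") <- params
  out
}

#' Two-interval forced-choice observer
#'
#' Log-logistic psychometric observer for the discrimination tasks:
#' `p_correct(d) = guess + (1 - guess - lapse) *
#' logistic((log d - log threshold) / slope)`. At `d = threshold` the observer
#' is halfway between chance and its lapse-limited ceiling (75% correct with
#' the defaults); performance approaches `guess` as d -> 0 and `1 - lapse` as
#' d -> Inf.
#'
#' @param threshold Positive difference at the psychometric midpoint, in the
#'   task's units.
#' @param slope Logistic scale in log-difference units (default 0.5, a typical
#'   shallow discrimination slope).
#' @param lapse Lapse rate in \[0, 0.1\] (default 0).
#' @param guess Chance level (fixed at 0.5 for two-interval forced choice).
#' @return List of class `observer_params`.
#' @export
observer_params <- function(threshold, slope = 0.5, lapse = 0, guess = 0.5) {
  if (!is_number(threshold) || threshold <= 0)
    abort("threshold must be positive", "adaptaaf_invalid_config")
  if (!is_number(slope) || slope <= 0)
    abort("slope must be positive", "adaptaaf_invalid_config")
  if (!is_number(lapse) || lapse < 0 || lapse > 0.1)
    abort("lapse must be in [0, 0.1]", "adaptaaf_invalid_config")
  if (!is_number(guess) || guess < 0 || guess >= 1)
    abort("guess must be in [0, 1)", "adaptaaf_invalid_config")
  structure(list(threshold = threshold, slope = slope, lapse = lapse, guess = guess),
            class = "observer_params")
}

#' Observer percent-correct at a stimulus difference
#'
#' @param params An [observer_params()].
#' @param difference Positive stimulus difference(s).
#' @return Probability correct, in `[guess, 1 - lapse]`; vectorized.
#' @export
observer_p_correct <- function(params, difference) {
  if (!inherits(params, "observer_params"))
    abort("params must be observer_params", "adaptaaf_invalid_config")
  if (!is.numeric(difference) || length(difference) < 1L || anyNA(difference) ||
      any(!is.finite(difference)) || any(difference <= 0))
    abort("difference must be positive", "adaptaaf_invalid_input")
  params$guess + (1 - params$guess - params$lapse) *
    stats::plogis((log(difference) - log(params$threshold)) / params$slope)
}

#' Simulate a conflict-task trial table
#'
#' Gaussian reaction times with condition means `base_rt - congruency_gain`
#' (congruent), `base_rt` (neutral) and `base_rt + incongruity_cost`
#' (incongruent); correctness is Bernoulli with rate `1 - error_rate`. With
#' zero noise and error rate, [conflict_scores()] on the result returns
#' interference `-(congruency_gain + incongruity_cost)` exactly.
#'
#' @param n_per_condition Trials per condition (default 16, the 48-trial task).
#' @param base_rt Neutral-condition mean RT, ms (default 500).
#' @param congruency_gain Speed-up of congruent trials, ms (default 20).
#' @param incongruity_cost Slow-down of incongruent trials, ms (default 30).
#' @param sd RT standard deviation, ms (default 100).
#' @param error_rate Per-trial error probability (default 0.02).
#' @param task Optional task label carried in a `task` column.
#' @param seed Optional integer seed.
#' @return Data frame: `task`, `condition`, `rt_ms`, `correct`.
#' @export
simulate_rt_table <- function(n_per_condition = 16L, base_rt = 500,
                              congruency_gain = 20, incongruity_cost = 30,
                              sd = 100, error_rate = 0.02,
                              task = NA_character_, seed = NULL) {
  if (!is_count(n_per_condition, 2))
    abort("n_per_condition must be >= 2", "adaptaaf_invalid_config")
  if (!is_number(sd) || sd < 0) abort("sd must be >= 0", "adaptaaf_invalid_config")
  if (!is_number(error_rate) || error_rate < 0 || error_rate > 1)
    abort("error_rate must be in [0, 1]", "adaptaaf_invalid_config")
  if (!is.null(seed)) set.seed(seed)
  means <- c(congruent = base_rt - congruency_gain, neutral = base_rt,
             incongruent = base_rt + incongruity_cost)
  n <- 3L * n_per_condition
  cond <- rep(names(means), each = n_per_condition)
  rt <- pmax(stats::rnorm(n, rep(unname(means), each = n_per_condition), sd), 1)
  data.frame(task = task, condition = cond, rt_ms = rt,
             correct = stats::runif(n) >= error_rate)
}

MAJOR_PC <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)

in_key <- function(notes, tonic) ((notes - tonic) %% 12L) %in% MAJOR_PC

contour_ok <- function(notes, j, q) {
  # changing notes[j] to q must preserve the signs of both adjacent intervals
  (j == 1L || sign(q - notes[j - 1L]) == sign(notes[j] - notes[j - 1L])) &&
    (j == length(notes) || sign(notes[j + 1L] - q) == sign(notes[j + 1L] - notes[j]))
}

#' Generate a melody discrimination stimulus pair
#'
#' The first melody is a random walk on a sampled major scale (5-13 notes,
#' integer semitones, adjacent notes distinct and at most 5 semitones apart).
#' Simple task: "same" pairs repeat the melody; "different" pairs move exactly
#' one note by up to +-5 semitones, staying in key and preserving the melodic
#' contour (the signs of successive intervals). Transposed task: the second
#' melody is transposed 4 semitones up; in "different" pairs one note is
#' additionally moved by 1 semitone to a pitch outside the transposed key,
#' contour preserved.
#'
#' @param n_notes Number of notes, 5-13.
#' @param trial_type `"same"` or `"different"`.
#' @param transposed Logical: transposed-task pair?
#' @param seed Optional integer seed.
#' @param max_attempts Melody resampling budget before giving up (default 100).
#' @return List of class `melody_pair`: `notes_a`, `notes_b` (integer
#'   semitones), `trial_type`, `transposed`, `changed_index` (NA for "same"),
#'   `tonic`.
#' @export
generate_melody_pair <- function(n_notes, trial_type = c("same", "different"),
                                 transposed = FALSE, seed = NULL,
                                 max_attempts = 100L) {
  trial_type <- match.arg(trial_type)
  if (!is_count(n_notes, 5) || n_notes > 13L)
    abort("n_notes must be between 5 and 13", "adaptaaf_invalid_config")
  if (!is.null(seed)) set.seed(seed)

  for (attempt in seq_len(max_attempts)) {
    tonic <- sample(48:59, 1L)
    scale_notes <- sort(tonic + as.vector(outer(MAJOR_PC, c(0L, 12L), `+`)))
    notes <- sample(scale_notes[4:10], 1L)
    for (k in 2:n_notes) {
      prev <- notes[k - 1L]
      cand <- scale_notes[abs(scale_notes - prev) <= 5L & scale_notes != prev]
      notes[k] <- cand[sample.int(length(cand), 1L)]
    }

    base_b <- notes + if (transposed) 4L else 0L
    if (trial_type == "same") {
      return(structure(list(notes_a = notes, notes_b = base_b,
                            trial_type = trial_type, transposed = transposed,
                            changed_index = NA_integer_, tonic = tonic),
                       class = "melody_pair"))
    }
    key_tonic <- tonic + if (transposed) 4L else 0L
    for (j in sample.int(n_notes)) {
      cand <- if (transposed) {
        q <- base_b[j] + c(-1L, 1L)
        q[!in_key(q, key_tonic)]
      } else {
        q <- setdiff(scale_notes[abs(scale_notes - base_b[j]) <= 5L], base_b[j])
        q
      }
      cand <- cand[vapply(cand, function(q) contour_ok(base_b, j, q), logical(1L))]
      if (length(cand)) {
        notes_b <- base_b
        notes_b[j] <- cand[sample.int(length(cand), 1L)]
        return(structure(list(notes_a = notes, notes_b = notes_b,
                              trial_type = trial_type, transposed = transposed,
                              changed_index = j, tonic = tonic),
                         class = "melody_pair"))
      }
    }
    # no position admits a key- and contour-preserving change: resample melody
  }
  abort("could not generate a valid melody pair within the attempt budget",
        "adaptaaf_melody_failure")
}

#' @export
print.melody_pair <- function(x, ...) {
  cat(sprintf("Melody pair (%s%s, %d notes, tonic %d)\n",
              x$trial_type, if (x$transposed) ", transposed +4" else "",
              length(x$notes_a), x$tonic))
  cat("  a:", paste(x$notes_a, collapse = " "), "\n")
  cat("  b:", paste(x$notes_b, collapse = " "),
      if (!is.na(x$changed_index)) sprintf(" (changed at %d)", x$changed_index) else "",
      "\n")
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Cohort specification
#'
#' Ground-truth generative model for a linked multi-task cohort. A latent
#' auditory acuity per participant drives the speaker's corrective gain and
#' dead zone, the pitch/loudness observer thresholds (log-linearly, thresholds
#' shrinking with acuity) and melody accuracy; executive interference effects
#' are drawn independently of acuity. Defaults are chosen so measured values
#' fall in realistic ranges: adaptation roughly 10-40% of the alteration,
#' pitch thresholds ~0.3-3%, loudness ~0.4-2 dB, melody accuracy ~65-90%,
#' interference medians a few tens of ms.
#'
#' @param n Number of participants (>= 2; default 31, the analyzed sample
#'   size).
#' @param seed Integer master seed; every random draw in the bundle flows from
#'   it via deterministic per-participant substreams.
#' @param acuity_range Uniform range of the latent acuity (default 0.05-0.95).
#' @param gain_base,gain_coupling Speaker gain = `gain_base + gain_coupling *
#'   acuity`.
#' @param anchor Speaker feedforward anchor (default 0.2).
#' @param dead_zone_scale Dead zone = `dead_zone_scale * (1 - acuity)` Hz.
#' @param noise_sd,failure_rate Speaker production noise (Hz) and tracking
#'   failure probability.
#' @param pitch_threshold_scale,loudness_threshold_scale Observer threshold at
#'   zero acuity, task units.
#' @param threshold_coupling Named vector (`pitch`, `loudness`):
#'   log-threshold decrease per unit acuity.
#' @param threshold_noise_sd SD of log-threshold noise across participants.
#' @param observer_slope,observer_lapse Psychometric observer shape.
#' @param staircase_runs Runs per acuity task (default 4).
#' @param melody_base,melody_coupling,melody_noise_sd Melody accuracy =
#'   `melody_base + melody_coupling * acuity + noise`, clamped to
#'   \[0.5, 0.98\].
#' @param melody_trials Trials per melody task (default 60).
#' @param rt_n_per_condition,rt_base,rt_sd,rt_error_rate Conflict-task trial
#'   structure.
#' @param congruency_gain_mean,congruency_gain_sd,incongruity_cost_mean,incongruity_cost_sd
#'   Across-participant distribution of the true RT effects (independent of
#'   acuity; truncated at 0).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 31L, seed = 1L,
                        acuity_range = c(0.05, 0.95),
                        gain_base = 0.02, gain_coupling = 0.12, anchor = 0.2,
                        dead_zone_scale = 120,
                        noise_sd = 10, failure_rate = 0.01,
                        pitch_threshold_scale = 3.0,
                        loudness_threshold_scale = 2.0,
                        threshold_coupling = c(pitch = 2.0, loudness = 1.5),
                        threshold_noise_sd = 0.15,
                        observer_slope = 0.5, observer_lapse = 0.02,
                        staircase_runs = 4L,
                        melody_base = 0.62, melody_coupling = 0.25,
                        melody_noise_sd = 0.03, melody_trials = 60L,
                        rt_n_per_condition = 16L, rt_base = 500, rt_sd = 100,
                        rt_error_rate = 0.02,
                        congruency_gain_mean = 15, congruency_gain_sd = 8,
                        incongruity_cost_mean = 30, incongruity_cost_sd = 15) {
  if (!is_count(n, 2)) abort("n must be >= 2", "adaptaaf_invalid_config")
  if (!is_count(seed, 0)) abort("seed must be a non-negative integer", "adaptaaf_invalid_config")
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a linked synthetic cohort
#'
#' For each participant: a formant track from the acuity-coupled speaker model
#' under the default perturbation schedule; `staircase_runs` simulated
#' staircase runs per acuity task against observers whose true thresholds are
#' acuity-coupled; binomial melody-task accuracies; and three conflict-task
#' trial tables (Stroop, Simon, Flanker) whose true effects are independent of
#' acuity. Every latent parameter is recorded in the ground-truth table.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `aaf_cohort`: `formants`, `staircase` (per-run
#'   thresholds), `melody`, `rt_trials`, `ground_truth`, plus the `spec` and
#'   the `schedule` used.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec"))
    abort("spec must be a cohort_spec", "adaptaaf_invalid_config")
  set.seed(spec$seed)
  schedule <- build_schedule()
  n <- spec$n
  acuity <- stats::runif(n, spec$acuity_range[1L], spec$acuity_range[2L])
  subseeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("P%03d", seq_len(n))
  exec_tasks <- c("stroop", "simon", "flanker")
  acuity_tasks <- c(pitch = spec$pitch_threshold_scale,
                    loudness = spec$loudness_threshold_scale)

  formants <- staircase <- melody <- rt_trials <- truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subseeds[i])
    a <- acuity[i]

    thr_true <- vapply(names(acuity_tasks), function(task)
      acuity_tasks[[task]] * exp(-spec$threshold_coupling[[task]] * a +
                                   stats::rnorm(1L, 0, spec$threshold_noise_sd)),
      numeric(1L))
    p_mel <- clamp(spec$melody_base + spec$melody_coupling * a +
                     stats::rnorm(1L, 0, spec$melody_noise_sd), 0.5, 0.98)
    p_simple <- clamp(p_mel + 0.015, 0.5, 0.98)
    p_transposed <- clamp(p_mel - 0.015, 0.5, 0.98)
    gains <- pmax(stats::rnorm(3L, spec$congruency_gain_mean, spec$congruency_gain_sd), 0)
    costs <- pmax(stats::rnorm(3L, spec$incongruity_cost_mean, spec$incongruity_cost_sd), 0)

    speaker <- speaker_params(acuity = a,
                              gain = spec$gain_base + spec$gain_coupling * a,
                              anchor = spec$anchor,
                              dead_zone_hz = spec$dead_zone_scale * (1 - a),
                              noise_sd = spec$noise_sd,
                              failure_rate = spec$failure_rate)
    tr <- simulate_speaker(speaker, schedule)
    formants[[i]] <- data.frame(participant = ids[i], tr)

    obs <- lapply(thr_true, function(th)
      observer_params(th, spec$observer_slope, spec$observer_lapse))
    staircase[[i]] <- do.call(rbind, lapply(names(obs), function(task) {
      cfg <- staircase_preset(task)
      data.frame(participant = ids[i], task = task,
                 run = seq_len(spec$staircase_runs),
                 threshold = vapply(seq_len(spec$staircase_runs), function(r)
                   run_threshold(simulate_staircase(obs[[task]], cfg), cfg),
                   numeric(1L)))
    }))

    n_mel <- spec$melody_trials
    correct_simple <- stats::rbinom(1L, n_mel, p_simple)
    correct_transposed <- stats::rbinom(1L, n_mel, p_transposed)
    melody[[i]] <- data.frame(participant = ids[i],
                              task = c("simple", "transposed"),
                              n_trials = n_mel,
                              n_correct = c(correct_simple, correct_transposed),
                              pct = 100 * c(correct_simple, correct_transposed) / n_mel)

    rt_trials[[i]] <- do.call(rbind, lapply(seq_along(exec_tasks), function(k)
      data.frame(participant = ids[i],
                 simulate_rt_table(spec$rt_n_per_condition, spec$rt_base,
                                   gains[k], costs[k], spec$rt_sd,
                                   spec$rt_error_rate, task = exec_tasks[k]))))

    truth[[i]] <- data.frame(
      participant = ids[i], acuity = a,
      gain = speaker$gain, anchor = speaker$anchor,
      dead_zone_hz = speaker$dead_zone_hz,
      fixed_point_pct = 100 * speaker$gain / (speaker$gain + speaker$anchor),
      pitch_threshold_true = thr_true[["pitch"]],
      loudness_threshold_true = thr_true[["loudness"]],
      melody_p_true = p_mel,
      interference_stroop_true = -(gains[1L] + costs[1L]),
      interference_simon_true = -(gains[2L] + costs[2L]),
      interference_flanker_true = -(gains[3L] + costs[3L]))
  }
  structure(list(formants = do.call(rbind, formants),
                 staircase = do.call(rbind, staircase),
                 melody = do.call(rbind, melody),
                 rt_trials = do.call(rbind, rt_trials),
                 ground_truth = do.call(rbind, truth),
                 spec = spec, schedule = schedule),
            class = "aaf_cohort")
}

#' @export
print.aaf_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (seed %d)\n", x$spec$n, x$spec$seed))
  cat(sprintf("  %d formant trials, %d staircase runs, %d RT trials\n",
              nrow(x$formants), nrow(x$staircase), nrow(x$rt_trials)))
  invisible(x)
}

#' Run the full measurement pipeline on a synthetic cohort
#'
#' Produces the per-participant measure table the regression stage consumes:
#' adaptation and aftereffect from the formant pipeline, session thresholds
#' (median over runs) per acuity task, melody percent-correct per task, and
#' the interference effect per conflict task.
#'
#' @param bundle An [generate_cohort()] result.
#' @param ... Passed to [process_formants()].
#' @return Data frame, one row per (non-excluded) participant.
#' @export
analyze_cohort <- function(bundle, ...) {
  if (!inherits(bundle, "aaf_cohort"))
    abort("bundle must be an aaf_cohort", "adaptaaf_invalid_config")
  fm <- process_formants(bundle$formants, ...)
  meas <- fm$summaries[!fm$summaries$excluded,
                       c("participant", "adaptation_hz", "aftereffect_hz",
                         "adaptation_pct", "aftereffect_pct")]

  st <- aggregate(threshold ~ participant + task, bundle$staircase, session_threshold)
  for (task in unique(st$task)) {
    col <- paste0(task, "_threshold")
    sub <- st[st$task == task, c("participant", "threshold")]
    names(sub)[2L] <- col
    meas <- merge(meas, sub, by = "participant")
  }

  for (task in unique(bundle$melody$task)) {
    sub <- bundle$melody[bundle$melody$task == task, c("participant", "pct")]
    names(sub)[2L] <- paste0("melody_", task, "_pct")
    meas <- merge(meas, sub, by = "participant")
  }

  rt <- bundle$rt_trials
  for (task in unique(rt$task)) {
    sub <- do.call(rbind, lapply(split(rt[rt$task == task, ], rt$participant[rt$task == task]),
      function(d) data.frame(participant = d$participant[1L],
                             x = score_conflict_task(d)$interference_ms)))
    names(sub)[2L] <- paste0("interference_", task)
    meas <- merge(meas, sub, by = "participant")
  }
  rownames(meas) <- NULL
  meas
}

#' Regression models linking acuity and executive measures to adaptation
#'
#' `adaptation_model` screens the six candidate predictors (three interference
#' effects, two discrimination thresholds, two melody scores merged into one
#' combined score when significantly correlated) and backward-eliminates a
#' standardized regression of median adaptation on them. `aftereffect_model`
#' does the same for median aftereffect with median adaptation added as a
#' seventh predictor.
#'
#' @param measures Per-participant measure table from [analyze_cohort()] (or
#'   equivalent real data).
#' @param p_remove Backward-elimination threshold (default 0.10).
#' @param p_corr Melody-merge significance threshold (default 0.05).
#' @return List: `screening` ([screen_predictors()] result) and `elimination`
#'   ([backward_eliminate()] result).
#' @export
adaptation_model <- function(measures, p_remove = 0.10, p_corr = 0.05) {
  outcome_model(measures, "adaptation_hz", extra = character(0L),
                p_remove = p_remove, p_corr = p_corr)
}

#' @rdname adaptation_model
#' @export
aftereffect_model <- function(measures, p_remove = 0.10, p_corr = 0.05) {
  outcome_model(measures, "aftereffect_hz", extra = "adaptation_hz",
                p_remove = p_remove, p_corr = p_corr)
}

outcome_model <- function(measures, outcome, extra, p_remove, p_corr) {
  base_preds <- c("interference_stroop", "interference_simon", "interference_flanker",
                  "loudness_threshold", "pitch_threshold",
                  "melody_simple_pct", "melody_transposed_pct")
  check_numeric_cols(measures, c(outcome, base_preds, extra))
  scr <- screen_predictors(measures[base_preds], p_corr = p_corr)
  d <- cbind(scr$data, measures[c(extra, outcome)])
  predictors <- c(names(scr$data), extra)
  list(screening = scr,
       elimination = backward_eliminate(d, outcome, predictors, p_remove))
}

#' Write a cohort bundle to a directory of CSV files
#'
#' Writes `formants.csv` (in the `participant,trial,f1_hz,f2_hz,valid` trial
#' format), `staircase_runs.csv`, `melody.csv`, `rt_trials.csv`,
#' `ground_truth.csv` and a JSON `manifest.json` recording the generating
#' specification and seed.
#'
#' @param bundle An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!inherits(bundle, "aaf_cohort"))
    abort("bundle must be an aaf_cohort", "adaptaaf_invalid_config")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_formant_tracks(bundle$formants, file.path(dir, "formants.csv"))
  utils::write.csv(bundle$staircase, file.path(dir, "staircase_runs.csv"), row.names = FALSE)
  utils::write.csv(bundle$melody, file.path(dir, "melody.csv"), row.names = FALSE)
  utils::write.csv(bundle$rt_trials, file.path(dir, "rt_trials.csv"), row.names = FALSE)
  utils::write.csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(bundle$spec), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
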