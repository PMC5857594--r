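# Transformed 2-down/1-up adaptive staircase with multiplicative steps, as used
# by the pitch and loudness discrimination tasks. The difference between the
# two stimuli of a trial is divided by the current step factor after n_down
# consecutive correct responses and multiplied by it after each error; the
# procedure brackets the ~70.7%-correct point of the observer's psychometric
# function. Thresholds are geometric means of late reversal values.

#' Staircase configuration
#'
#' @param initial_difference Starting stimulus difference (task units: percent
#'   frequency difference for pitch, dB for loudness). Must be positive.
#' @param initial_step_factor,reduced_step_factor Multiplicative step factors;
#'   the initial factor (2) converges quickly, and after
#'   `reversals_before_reduction` reversals the reduced factor (1.25) refines
#'   the estimate. Both must exceed 1.
#' @param reversals_before_reduction Reversals after which the step factor is
#'   reduced (default 2).
#' @param total_reversals Reversals that complete a run (default 15).
#' @param reversals_for_threshold Number of final reversals entering the
#'   geometric-mean threshold (default 8); the early reversals are discarded so
#'   the threshold does not depend on the starting difference.
#' @param n_down Consecutive correct responses required to step down (default
#'   2); `n_up` errors step up (default 1).
#' @param n_up See `n_down`.
#' @param reference Reference stimulus magnitude (metadata; e.g. 500 Hz tone,
#'   65 dB SPL).
#' @param units Unit label for differences (metadata).
#' @param max_trials Safety cap on trials per run (default 400); a run that
#'   fails to finish within the cap is reported as a runaway staircase.
#' @return List of class `staircase_config`.
#' @seealso [staircase_preset()] for the pitch/loudness task presets.
#' @export
staircase_config <- function(initial_difference,
                             initial_step_factor = 2,
                             reduced_step_factor = 1.25,
                             reversals_before_reduction = 2L,
                             total_reversals = 15L,
                             reversals_for_threshold = 8L,
                             n_down = 2L, n_up = 1L,
                             reference = NULL, units = NULL,
                             max_trials = 400L) {
  if (!is_number(initial_difference) || initial_difference <= 0)
    abort("initial_difference must be positive", "adaptaaf_invalid_config")
  if (!is_number(initial_step_factor) || initial_step_factor <= 1 ||
      !is_number(reduced_step_factor) || reduced_step_factor <= 1)
    abort("step factors must be > 1", "adaptaaf_invalid_config")
  if (!is_count(reversals_before_reduction, 0) || !is_count(total_reversals) ||
      !is_count(reversals_for_threshold) || !is_count(n_down) || !is_count(n_up) ||
      !is_count(max_trials))
    abort("staircase counts must be positive whole numbers", "adaptaaf_invalid_config")
  if (reversals_for_threshold > total_reversals)
    abort("reversals_for_threshold cannot exceed total_reversals", "adaptaaf_invalid_config")
  if (n_up != 1L)
    abort("only 1-up rules are supported (the difference steps up after every error)",
          "adaptaaf_invalid_config")
  structure(list(initial_difference = initial_difference,
                 initial_step_factor = initial_step_factor,
                 reduced_step_factor = reduced_step_factor,
                 reversals_before_reduction = reversals_before_reduction,
                 total_reversals = total_reversals,
                 reversals_for_threshold = reversals_for_threshold,
                 n_down = n_down, n_up = n_up,
                 reference = reference, units = units,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' Staircase presets for the pitch and loudness discrimination tasks
#'
#' Pitch: 500 Hz reference tone, initial difference 7% of the reference
#' frequency. Loudness: 65 dB SPL reference, initial difference 10 dB. Both use
#' step factor 2 reduced to 1.25 after two reversals, 15 reversals per run, and
#' the geometric mean of the last 8 reversals as the run threshold.
#'
#' @param task `"pitch"` or `"loudness"`.
#' @return A [staircase_config()].
#' @export
staircase_preset <- function(task = c("pitch", "loudness")) {
  task <- match.arg(task)
  switch(task,
    pitch = staircase_config(initial_difference = 7, reference = 500,
                             units = "% frequency difference"),
    loudness = staircase_config(initial_difference = 10, reference = 65,
                                units = "dB"))
}

#' Create a fresh staircase state
#'
#' @param config A [staircase_config()].
#' @return List of class `staircase_state`: current `difference`, consecutive
#'   correct counter, last move direction, reversal values, per-trial log
#'   (`difference`, `correct`, `reversal`) and the `finished` flag.
#' @export
new_staircase <- function(config) {
  if (!inherits(config, "staircase_config"))
    abort("config must be a staircase_config", "adaptaaf_invalid_config")
  structure(list(difference = config$initial_difference,
                 n_correct = 0L,
                 last_move = "none",
                 reversals = numeric(0L),
                 log_difference = numeric(0L),
                 log_correct = logical(0L),
                 log_reversal = logical(0L),
                 finished = FALSE),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' An error multiplies the difference by the current step factor; the
#' `n_down`-th consecutive correct response divides it (intermediate correct
#' responses leave it unchanged). A reversal is recorded whenever the move
#' direction flips, at the difference the staircase moves to; the step factor
#' drops to the reduced factor once `reversals_before_reduction` reversals have
#' been recorded, and the run finishes at `total_reversals` reversals.
#'
#' @param state A `staircase_state` (not finished).
#' @param config The run's [staircase_config()].
#' @param correct Logical: was the response correct?
#' @return Updated `staircase_state`.
#' @export
staircase_update <- function(state, config, correct) {
  if (!inherits(state, "staircase_state"))
    abort("state must be a staircase_state", "adaptaaf_invalid_config")
  if (state$finished)
    abort("cannot update a finished staircase run", "adaptaaf_state_error")
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct))
    abort("correct must be TRUE or FALSE", "adaptaaf_invalid_config")

  factor <- if (length(state$reversals) >= config$reversals_before_reduction)
    config$reduced_step_factor else config$initial_step_factor

  presented <- state$difference
  move <- NULL
  if (!correct) {
    state$n_correct <- 0L
    new_diff <- presented * factor
    move <- "up"
  } else {
    state$n_correct <- state$n_correct + 1L
    if (state$n_correct >= config$n_down) {
      state$n_correct <- 0L
      new_diff <- presented / factor
      move <- "down"
    }
  }

  reversal <- FALSE
  if (!is.null(move)) {
    if (state$last_move != "none" && move != state$last_move) {
      reversal <- TRUE
      state$reversals <- c(state$reversals, new_diff)
      if (length(state$reversals) >= config$total_reversals)
        state$finished <- TRUE
    }
    state$last_move <- move
    state$difference <- new_diff
  }
  state$log_difference <- c(state$log_difference, presented)
  state$log_correct <- c(state$log_correct, correct)
  state$log_reversal <- c(state$log_reversal, reversal)
  state
}

#' Threshold of one completed staircase run
#'
#' Geometric mean of the final `reversals_for_threshold` reversal values; the
#' earlier reversals are not entered, which makes the run threshold insensitive
#' to the starting difference.
#'
#' @param state A finished `staircase_state`.
#' @param config The run's [staircase_config()].
#' @return Positive scalar threshold, in the task's difference units.
#' @export
run_threshold <- function(state, config) {
  if (!inherits(state, "staircase_state"))
    abort("state must be a staircase_state", "adaptaaf_invalid_config")
  if (!state$finished)
    abort("run_threshold requires a finished run", "adaptaaf_state_error")
  k <- config$reversals_for_threshold
  if (length(state$reversals) < k)
    abort(sprintf("need at least %d reversals", k), "adaptaaf_state_error")
  exp(mean(log(utils::tail(state$reversals, k))))
}

#' Session threshold across runs
#'
#' Aggregates the per-run geometric-mean thresholds of a session (four runs per
#' task in the reference design). The median is the session statistic entered
#' into regression analyses; the mean is available as an option.
#'
#' @param runs Numeric vector of run thresholds (length >= 1).
#' @param method `"median"` (default) or `"mean"`.
#' @return Positive scalar.
#' @export
session_threshold <- function(runs, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!is.numeric(runs) || length(runs) < 1L || anyNA(runs) || any(runs <= 0))
    abort("runs must be a non-empty vector of positive thresholds", "adaptaaf_invalid_input")
  if (method == "median") stats::median(runs) else mean(runs)
}

#' Simulate a staircase run against a psychometric observer
#'
#' Drives [staircase_update()] with Bernoulli responses drawn from the
#' observer's percent-correct function at the currently presented difference.
#' A run that does not complete within `config$max_trials` trials (e.g. a
#' guessing observer that never produces reversals) raises a runaway-staircase
#' error.
#'
#' @param observer An [observer_params()].
#' @param config A [staircase_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Finished `staircase_state`.
#' @export
simulate_staircase <- function(observer, config, seed = NULL) {
  if (!inherits(config, "staircase_config"))
    abort("config must be a staircase_config", "adaptaaf_invalid_config")
  if (!inherits(observer, "observer_params"))
    abort("observer must be observer_params", "adaptaaf_invalid_config")
  if (!is.null(seed)) set.seed(seed)

  # tight inline loop with semantics identical to repeated staircase_update()
  # (asserted by an equivalence test); simulations drive thousands of runs
  guess <- observer$guess
  ceil <- 1 - observer$guess - observer$lapse
  lth <- log(observer$threshold)
  sl <- observer$slope
  fac_init <- config$initial_step_factor
  fac_red <- config$reduced_step_factor
  rbr <- config$reversals_before_reduction
  total <- config$total_reversals
  n_down <- config$n_down
  max_trials <- config$max_trials

  d <- config$initial_difference
  n_correct <- 0L
  last_move <- 0L # 0 none, 1 down, 2 up
  nrev <- 0L
  revs <- numeric(total)
  log_d <- numeric(max_trials)
  log_c <- logical(max_trials)
  log_r <- logical(max_trials)
  trial <- 0L
  finished <- FALSE
  while (!finished) {
    if (trial >= max_trials)
      abort(sprintf("staircase did not finish within %d trials", max_trials),
            "adaptaaf_runaway_staircase")
    trial <- trial + 1L
    p <- guess + ceil / (1 + exp(-(log(d) - lth) / sl))
    correct <- stats::runif(1L) < p
    fac <- if (nrev >= rbr) fac_red else fac_init
    move <- 0L
    if (!correct) {
      n_correct <- 0L
      new_d <- d * fac
      move <- 2L
    } else {
      n_correct <- n_correct + 1L
      if (n_correct >= n_down) {
        n_correct <- 0L
        new_d <- d / fac
        move <- 1L
      }
    }
    reversal <- FALSE
    log_d[trial] <- d
    log_c[trial] <- correct
    if (move != 0L) {
      if (last_move != 0L && move != last_move) {
        reversal <- TRUE
        nrev <- nrev + 1L
        revs[nrev] <- new_d
        if (nrev >= total) finished <- TRUE
      }
      last_move <- move
      d <- new_d
    }
    log_r[trial] <- reversal
  }
  structure(list(difference = d,
                 n_correct = n_correct,
                 last_move = c("none", "down", "up")[last_move + 1L],
                 reversals = revs[seq_len(nrev)],
                 log_difference = log_d[seq_len(trial)],
                 log_correct = log_c[seq_len(trial)],
                 log_reversal = log_r[seq_len(trial)],
                 finished = finished),
            class = "staircase_state")
}

#' Simulate a multi-run staircase session
#'
#' @param observer An [observer_params()].
#' @param config A [staircase_config()].
#' @param runs Number of runs (default 4).
#' @param seed Optional integer seed.
#' @param method Session aggregate, `"median"` (default) or `"mean"`.
#' @return List: `run_thresholds` (length `runs`) and `session_threshold`.
#' @export
simulate_session <- function(observer, config, runs = 4L, seed = NULL,
                             method = c("median", "mean")) {
  if (!is_count(runs)) abort("runs must be >= 1", "adaptaaf_invalid_config")
  if (!is.null(seed)) set.seed(seed)
  th <- vapply(seq_len(runs), function(i)
    run_threshold(simulate_staircase(observer, config), config), numeric(1L))
  list(run_thresholds = th, session_threshold = session_threshold(th, method))
}

#' Export a staircase run log
#'
#' @param state A `staircase_state`.
#' @return Data frame with columns `trial`, `difference` (as presented),
#'   `correct`, `reversal`.
#' @export
staircase_log <- function(state) {
  if (!inherits(state, "staircase_state"))
    abort("state must be a staircase_state", "adaptaaf_invalid_config")
  data.frame(trial = seq_along(state$log_difference),
             difference = state$log_difference,
             correct = state$log_correct,
             reversal = state$log_reversal)
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("Staircase run: %d trials, %d reversals, %s\n",
              length(x$log_difference), length(x$reversals),
              if (x$finished) "finished" else
                sprintf("running (difference %.4g)", x$difference)))
  invisible(x)
}
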