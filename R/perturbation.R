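# Perturbation schedule: the experiment's independent variable. Feedback
# alteration is a signed (F1, F2) offset in Hz added to the speaker's produced
# formants before playback; the schedule fixes that offset per trial across
# four phases (baseline, ramp, hold, end).

as_alteration <- function(v) {
  if (!is.numeric(v) || length(v) != 2L || anyNA(v) || any(!is.finite(v)))
    abort("an alteration vector must be two finite numbers: c(f1_shift, f2_shift) in Hz",
          "adaptaaf_invalid_config")
  stats::setNames(as.numeric(v), c("f1_shift", "f2_shift"))
}

#' Euclidean magnitude of an alteration vector
#'
#' The magnitude of the feedback alteration in Hz, used to normalize
#' compensation values into percent-of-alteration. For the maximal alteration
#' used in the vowel experiment, `c(-150, 300)`, the magnitude is
#' `sqrt(150^2 + 300^2) = 335.41` Hz.
#'
#' @param v Numeric length-2 vector `c(f1_shift, f2_shift)` in Hz.
#' @return Non-negative scalar, Hz.
#' @examples
#' alteration_magnitude(c(-150, 300))
#' alteration_magnitude(c(3, 4))
#' @export
alteration_magnitude <- function(v) {
  v <- as_alteration(v)
  sqrt(sum(v^2))
}

#' Build the four-phase feedback-alteration schedule
#'
#' Constructs the per-trial (F1, F2) feedback shift for a session with
#' consecutive baseline, ramp, hold, and end phases. Baseline and end trials
#' are unshifted; ramp trial k (k = 1..`n_ramp`) carries `k/n_ramp` of
#' `max_shift` per formant, so the maximum is reached exactly at the last ramp
#' trial; hold trials carry `max_shift`. With the defaults (20/20/40/20 trials,
#' maximal shift (-150, +300) Hz) the ramp advances by -7.5 Hz in F1 and
#' +15 Hz in F2 per trial.
#'
#' @param n_baseline,n_ramp,n_hold,n_end Phase lengths in trials (all >= 1).
#' @param max_shift Maximal alteration `c(f1_shift, f2_shift)` in Hz.
#' @return A data frame of class `perturbation_schedule` with columns
#'   `trial` (1-based, contiguous), `phase` (factor: baseline, ramp, hold,
#'   end), `f1_shift`, `f2_shift` (Hz).
#' @examples
#' sched <- build_schedule()
#' sched[c(20, 21, 40, 41, 80, 81), ]
#' @export
build_schedule <- function(n_baseline = 20L, n_ramp = 20L, n_hold = 40L,
                           n_end = 20L, max_shift = c(-150, 300)) {
  counts <- c(n_baseline = n_baseline, n_ramp = n_ramp,
              n_hold = n_hold, n_end = n_end)
  if (!all(vapply(counts, is_count, logical(1L))))
    abort("phase lengths must be positive whole numbers", "adaptaaf_invalid_config")
  max_shift <- as_alteration(max_shift)
  ramp_frac <- seq_len(n_ramp) / n_ramp
  out <- data.frame(
    trial = seq_len(sum(counts)),
    phase = factor(rep(c("baseline", "ramp", "hold", "end"), counts),
                   levels = c("baseline", "ramp", "hold", "end")),
    f1_shift = c(rep(0, n_baseline), ramp_frac * max_shift[[1L]],
                 rep(max_shift[[1L]], n_hold), rep(0, n_end)),
    f2_shift = c(rep(0, n_baseline), ramp_frac * max_shift[[2L]],
                 rep(max_shift[[2L]], n_hold), rep(0, n_end))
  )
  attr(out, "max_shift") <- max_shift
  class(out) <- c("perturbation_schedule", "data.frame")
  out
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  ph <- table(x$phase)
  ms <- attr(x, "max_shift")
  cat(sprintf("Perturbation schedule: %d trials (%s)\n", nrow(x),
              paste(sprintf("%s %d", names(ph), ph), collapse = ", ")))
  cat(sprintf("  maximal alteration: F1 %+g Hz, F2 %+g Hz (|v| = %.2f Hz)\n",
              ms[[1L]], ms[[2L]], alteration_magnitude(ms)))
  invisible(x)
}

#' Read or write a perturbation schedule as CSV
#'
#' The on-disk format has columns `trial,phase,f1_shift_hz,f2_shift_hz`.
#'
#' @param schedule A `perturbation_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `perturbation_schedule`; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  out <- data.frame(trial = schedule$trial, phase = as.character(schedule$phase),
                    f1_shift_hz = schedule$f1_shift, f2_shift_hz = schedule$f2_shift)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trial", "phase", "f1_shift_hz", "f2_shift_hz")
  if (!all(need %in% names(d)))
    abort(sprintf("schedule CSV must have columns %s", paste(need, collapse = ",")),
          "adaptaaf_invalid_config")
  if (any(d$trial != seq_len(nrow(d))))
    abort("schedule trials must be contiguous and 1-based", "adaptaaf_invalid_config")
  out <- data.frame(
    trial = d$trial,
    phase = factor(d$phase, levels = c("baseline", "ramp", "hold", "end")),
    f1_shift = d$f1_shift_hz, f2_shift = d$f2_shift_hz
  )
  hold <- out$phase == "hold"
  ms <- if (any(hold)) c(out$f1_shift[hold][1L], out$f2_shift[hold][1L]) else c(0, 0)
  attr(out, "max_shift") <- as_alteration(ms)
  class(out) <- c("perturbation_schedule", "data.frame")
  out
}
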