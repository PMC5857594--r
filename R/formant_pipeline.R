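# Formant-track preprocessing and the scalar-projection compensation metric.
#
# A formant track is a data frame with columns `trial` (1-based, ascending),
# `f1`, `f2` (Hz, NA where the tracker failed). Multi-participant tables add a
# `participant` column. Processing order: discard equilibration trials ->
# screen for excessive tracking failure -> interpolate bounded gaps ->
# robust-smooth each formant -> baseline means -> per-trial scalar projection
# -> windowed medians.

check_track <- function(track, participant_ok = FALSE) {
  need <- c("trial", "f1", "f2")
  if (!is.data.frame(track) || !all(need %in% names(track)))
    abort("a formant track needs columns trial, f1, f2", "adaptaaf_invalid_config")
  if (anyNA(track$trial) || any(track$trial != trunc(track$trial)) ||
      any(diff(track$trial) <= 0))
    abort("track trial indices must be unique ascending integers", "adaptaaf_invalid_config")
  for (col in c("f1", "f2")) {
    v <- track[[col]]
    if (any(!is.na(v) & (!is.finite(v) | v <= 0)))
      abort(sprintf("present %s values must be positive and finite (use NA for missing)", col),
            "adaptaaf_invalid_config")
  }
  if (!participant_ok && "participant" %in% names(track) &&
      length(unique(track$participant)) > 1L)
    abort("expected a single participant's track", "adaptaaf_invalid_config")
  invisible(track)
}

#' Discard initial signal-equilibration trials
#'
#' Drops the first `n_discard` trials of a track (by position); remaining
#' trial indices are preserved, so a 100-trial session with `n_discard = 5`
#' yields a 95-trial track starting at trial 6.
#'
#' @param track Formant track data frame (`trial`, `f1`, `f2`).
#' @param n_discard Number of leading trials to drop (default 5).
#' @return The shortened track.
#' @export
discard_equilibration <- function(track, n_discard = 5L) {
  check_track(track)
  if (!is_count(n_discard, min = 0))
    abort("n_discard must be a non-negative whole number", "adaptaaf_invalid_config")
  if (n_discard >= nrow(track))
    abort("n_discard must leave at least one trial", "adaptaaf_invalid_config")
  if (n_discard == 0L) return(track)
  out <- track[-seq_len(n_discard), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpolate short runs of missing formant values
#'
#' Internal runs of at most `max_gap` consecutive missing trials are replaced,
#' per formant, by linear interpolation between the flanking valid trials
#' (via [zoo::na.approx()]). Longer internal runs are left missing and counted.
#' Leading/trailing missing runs, which have no two-sided boundary data, are
#' filled with the nearest valid value.
#'
#' @param track Formant track data frame.
#' @param max_gap Longest missing run that is interpolated (default 4).
#' @return The track with gaps filled; attributes `n_interpolated` and
#'   `n_unfilled` give per-formant counts of filled and still-missing cells.
#' @export
interpolate_missing <- function(track, max_gap = 4L) {
  check_track(track)
  if (!is_count(max_gap))
    abort("max_gap must be a positive whole number", "adaptaaf_invalid_config")
  n_int <- n_left <- c(f1 = 0L, f2 = 0L)
  for (col in c("f1", "f2")) {
    y <- track[[col]]
    if (all(is.na(y)))
      abort(sprintf("track has no valid %s values", col), "adaptaaf_unusable_track")
    filled <- zoo::na.approx(y, x = track$trial, maxgap = max_gap, na.rm = FALSE)
    ok <- which(!is.na(filled))
    if (ok[1L] > 1L) filled[seq_len(ok[1L] - 1L)] <- filled[ok[1L]]
    last <- ok[length(ok)]
    if (last < length(filled))
      filled[(last + 1L):length(filled)] <- filled[last]
    n_int[[col]] <- sum(is.na(y) & !is.na(filled))
    n_left[[col]] <- sum(is.na(filled))
    track[[col]] <- filled
  }
  attr(track, "n_interpolated") <- n_int
  attr(track, "n_unfilled") <- n_left
  track
}

#' Robust local-regression smoothing
#'
#' Smooths a sequence with locally weighted linear least squares: each point is
#' replaced by the value at that point of a degree-1 fit over its `span`
#' nearest neighbours, with tricube distance weights. Robustness reweighting
#' protects against tracking outliers: after each pass, residuals larger than
#' `outlier_mad` times the median absolute residual get hard zero weight and
#' smaller residuals are downweighted by Tukey's bisquare; the fit/reweight
#' cycle runs `iterations` times (or stops early once residuals vanish).
#' Constant and exactly linear sequences are reproduced unchanged.
#'
#' @param values Finite numeric sequence.
#' @param span Odd window size, `3 <= span <= length(values)` (default 5).
#' @param iterations Robustness iterations (default 5).
#' @param x Optional strictly increasing positions (default equally spaced);
#'   used when smoothing series with removed points.
#' @param outlier_mad Hard-rejection multiple of the median absolute residual
#'   (default 6).
#' @return Smoothed sequence, same length as `values`.
#' @export
robust_smooth <- function(values, span = 5L, iterations = 5L,
                          x = seq_along(values), outlier_mad = 6) {
  n <- length(values)
  if (!is.numeric(values) || n < 1L || anyNA(values) || any(!is.finite(values)))
    abort("values must be finite and non-missing", "adaptaaf_invalid_config")
  if (!is_count(span, min = 3) || span %% 2L == 0L || span > n)
    abort("span must be odd, >= 3 and no longer than the sequence", "adaptaaf_invalid_config")
  if (!is_count(iterations)) abort("iterations must be >= 1", "adaptaaf_invalid_config")
  if (length(x) != n || anyNA(x) || any(!is.finite(x)) || any(diff(x) <= 0))
    abort("x must be strictly increasing and match values in length", "adaptaaf_invalid_config")

  half <- (span - 1L) %/% 2L
  starts <- pmin(pmax(seq_len(n) - half, 1L), n - span + 1L)
  if (n > span && length(unique(round(diff(x), 10))) > 1L) {
    # non-uniform spacing: pick the contiguous window of `span` points whose
    # farthest member is closest to x[i]
    for (i in seq_len(n)) {
      cand <- max(1L, i - span + 1L):min(i, n - span + 1L)
      reach <- vapply(cand, function(s)
        max(abs(x[s:(s + span - 1L)] - x[i])), numeric(1L))
      starts[i] <- cand[which.min(reach)]
    }
  }
  idx <- outer(starts, 0:(span - 1L), `+`)
  xm <- matrix(x[idx], n)
  ym <- matrix(values[idx], n)
  d <- abs(xm - x)
  dmax <- d[, 1L]
  for (j in 2:span) dmax <- pmax(dmax, d[, j])
  dmax[dmax == 0] <- 1
  # tricube cutoff slightly beyond the farthest window point so every window
  # member keeps non-zero weight; otherwise zero-weighting an outlier can
  # leave its window with no usable neighbours on noiseless data
  tri <- (1 - pmin(d / (1.25 * dmax), 1)^3)^3

  rw <- rep(1, n)
  fit <- values
  scale0 <- max(1, stats::median(abs(values)))
  for (it in seq_len(iterations)) {
    w <- tri * matrix(rw[idx], n)
    sw <- rowSums(w)
    swx <- rowSums(w * xm)
    swy <- rowSums(w * ym)
    swxx <- rowSums(w * xm * xm)
    swxy <- rowSums(w * xm * ym)
    denom <- sw * swxx - swx^2
    ok <- is.finite(denom) & denom > 1e-10 * pmax(sw * swxx, 1e-300)
    b <- ifelse(ok, (sw * swxy - swx * swy) / denom, 0)
    a <- ifelse(sw > 0, (swy - b * swx) / sw, values)
    fit <- a + b * x
    if (it == iterations) break
    r <- values - fit
    m <- stats::median(abs(r))
    # on near-noiseless data the median absolute residual degenerates to ~0;
    # fall back to the mean absolute deviation so isolated spikes still get
    # zero weight without zeroing their (influenced but sound) neighbours
    if (m < 1e-10 * scale0) m <- mean(abs(r))
    if (m < 1e-10 * scale0) break
    u <- r / (outlier_mad * m)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  fit
}

#' Scalar projection of formant change onto the inverse-alteration direction
#'
#' The compensation statistic C: the component, in Hz, of a production's
#' formant change from baseline along the direction that opposes the feedback
#' alteration, `C = ((f1 - baseline_f1) * v1 + (f2 - baseline_f2) * v2) / |v|`
#' with `v = inverse_alteration`. Positive values mean the production opposes
#' the alteration; a change exactly equal to the inverse alteration (perfect
#' adaptation) projects to the full alteration magnitude, 335.41 Hz for the
#' default vectors. Vectorized over `f1`/`f2`; missing formants give NA.
#'
#' @param f1,f2 Produced formants, Hz (NA allowed, propagated).
#' @param baseline_f1,baseline_f2 Mean baseline formants, Hz.
#' @param inverse_alteration Length-2 direction opposing the alteration;
#'   default `c(150, -300)`, the inverse of the maximal (-150, +300) shift.
#' @return Signed compensation in Hz.
#' @examples
#' scalar_projection(650, 1500, 500, 1800)        # perfect adaptation: 335.41
#' scalar_projection(575, 1650, 500, 1800)        # half: 167.71
#' @export
scalar_projection <- function(f1, f2, baseline_f1, baseline_f2,
                              inverse_alteration = c(150, -300)) {
  v <- as_alteration(inverse_alteration)
  mag <- sqrt(sum(v^2))
  if (mag == 0)
    abort("inverse_alteration must be non-zero", "adaptaaf_invalid_config")
  if (!is_number(baseline_f1) || !is_number(baseline_f2))
    abort("baseline formants must be finite numbers", "adaptaaf_invalid_config")
  ((f1 - baseline_f1) * v[[1L]] + (f2 - baseline_f2) * v[[2L]]) / mag
}

#' Per-trial compensation series for one participant
#'
#' Computes baseline F1/F2 as the mean over `baseline_window` (trials 6-20 by
#' default) and projects every trial's formant change onto the
#' inverse-alteration direction.
#'
#' @param track Formant track (ideally interpolated and smoothed).
#' @param baseline_window Trial indices defining the baseline average.
#' @param inverse_alteration Direction opposing the alteration (see
#'   [scalar_projection()]).
#' @return Data frame of class `compensation_series` with columns `trial`, `c`
#'   (signed Hz); attributes `baseline_f1`, `baseline_f2`, `magnitude`.
#' @export
compensation_series <- function(track, baseline_window = 6:20,
                                inverse_alteration = c(150, -300)) {
  check_track(track)
  base <- track$trial %in% baseline_window
  if (!any(base))
    abort("baseline window contains no trials of this track", "adaptaaf_invalid_config")
  if (all(is.na(track$f1[base])) || all(is.na(track$f2[base])))
    abort("baseline window has no valid formant values", "adaptaaf_unusable_track")
  b1 <- mean(track$f1[base], na.rm = TRUE)
  b2 <- mean(track$f2[base], na.rm = TRUE)
  out <- data.frame(
    trial = track$trial,
    c = scalar_projection(track$f1, track$f2, b1, b2, inverse_alteration)
  )
  attr(out, "baseline_f1") <- b1
  attr(out, "baseline_f2") <- b2
  attr(out, "magnitude") <- alteration_magnitude(inverse_alteration)
  class(out) <- c("compensation_series", "data.frame")
  out
}

#' Windowed-median adaptation and aftereffect summary
#'
#' Adaptation is the median compensation over the late hold window (trials
#' 61-80 by default); the aftereffect is the median over the end window
#' (81-100). Each is also expressed as a percentage of the alteration
#' magnitude (100% = 335.41 Hz for the default alteration).
#'
#' @param series A [compensation_series()].
#' @param hold_window,end_window Trial indices for the two summaries.
#' @param magnitude Alteration magnitude in Hz used for the percentage scale;
#'   defaults to the magnitude stored in `series`.
#' @return One-row data frame: `adaptation_hz`, `aftereffect_hz`,
#'   `adaptation_pct`, `aftereffect_pct`.
#' @export
summarize_participant <- function(series, hold_window = 61:80,
                                  end_window = 81:100,
                                  magnitude = attr(series, "magnitude")) {
  if (!inherits(series, "compensation_series"))
    abort("series must be a compensation_series", "adaptaaf_invalid_config")
  if (!is_number(magnitude) || magnitude <= 0)
    abort("magnitude must be a positive number", "adaptaaf_invalid_config")
  win_median <- function(win, what) {
    sel <- series$trial %in% win
    if (!any(sel))
      abort(sprintf("%s window contains no trials", what), "adaptaaf_invalid_config")
    stats::median(series$c[sel], na.rm = TRUE)
  }
  adapt <- win_median(hold_window, "hold")
  after <- win_median(end_window, "end")
  data.frame(adaptation_hz = adapt, aftereffect_hz = after,
             adaptation_pct = 100 * adapt / magnitude,
             aftereffect_pct = 100 * after / magnitude)
}

#' Screen participants for excessive formant-tracking failure
#'
#' Participants whose fraction of missing trials (before interpolation)
#' exceeds `max_failed_fraction` are excluded; exactly at the threshold they
#' are kept (strict inequality).
#'
#' @param tracks Data frame with columns `participant`, `trial`, `f1`, `f2`.
#' @param max_failed_fraction Exclusion threshold in (0, 1], default 0.5.
#' @return List with `kept`/`excluded` (participant ids) and a `summary` data
#'   frame (`participant`, `n_trials`, `n_failed`, `failed_fraction`,
#'   `excluded`).
#' @export
screen_participants <- function(tracks, max_failed_fraction = 0.5) {
  if (!is.data.frame(tracks) || !all(c("participant", "trial", "f1", "f2") %in% names(tracks)))
    abort("tracks needs columns participant, trial, f1, f2", "adaptaaf_invalid_config")
  if (!is_number(max_failed_fraction) || max_failed_fraction <= 0 || max_failed_fraction > 1)
    abort("max_failed_fraction must be in (0, 1]", "adaptaaf_invalid_config")
  miss <- is.na(tracks$f1) | is.na(tracks$f2)
  agg <- aggregate(miss, list(participant = tracks$participant),
                   function(z) c(n = length(z), failed = sum(z)))
  summary <- data.frame(
    participant = agg$participant,
    n_trials = agg$x[, "n"],
    n_failed = agg$x[, "failed"]
  )
  summary$failed_fraction <- summary$n_failed / summary$n_trials
  summary$excluded <- summary$failed_fraction > max_failed_fraction
  list(kept = summary$participant[!summary$excluded],
       excluded = summary$participant[summary$excluded],
       summary = summary)
}

# plausibility bounds: flagged, never dropped
F1_BOUNDS <- c(100, 1200)
F2_BOUNDS <- c(500, 3500)

#' Full formant-processing pipeline
#'
#' Runs the complete per-participant chain on a multi-participant trial table:
#' discard the first `n_discard` equilibration trials, screen for excessive
#' tracking failure, interpolate bounded gaps, robust-smooth F1 and F2
#' separately, compute baseline means, project each trial onto the
#' inverse-alteration direction, and summarize adaptation/aftereffect as
#' windowed medians. Trials with formants outside plausible vowel ranges
#' (F1 100-1200 Hz, F2 500-3500 Hz) are counted but never dropped.
#'
#' @param tracks Data frame with columns `participant`, `trial`, `f1`, `f2`.
#' @param n_discard,max_gap,span,smooth_iterations Preprocessing parameters
#'   (see [discard_equilibration()], [interpolate_missing()],
#'   [robust_smooth()]).
#' @param baseline_window,hold_window,end_window Analysis windows (trial
#'   indices).
#' @param inverse_alteration Direction opposing the alteration.
#' @param max_failed_fraction Exclusion threshold for failed tracks.
#' @param smooth Set `FALSE` to skip robust smoothing (raw projections).
#' @return List of class `aaf_formant_results`: `summaries` (one row per
#'   participant with adaptation/aftereffect in Hz and percent, failure and
#'   interpolation counts, plausibility flags, exclusion flag), `series`
#'   (long per-trial compensation table for kept participants), and
#'   `screening` (from [screen_participants()]).
#' @export
process_formants <- function(tracks, n_discard = 5L, max_gap = 4L, span = 5L,
                             smooth_iterations = 5L,
                             baseline_window = 6:20, hold_window = 61:80,
                             end_window = 81:100,
                             inverse_alteration = c(150, -300),
                             max_failed_fraction = 0.5, smooth = TRUE) {
  if (!is.data.frame(tracks))
    abort("tracks must be a data frame", "adaptaaf_invalid_config")
  if (!"participant" %in% names(tracks)) tracks$participant <- "P1"
  ids <- unique(tracks$participant)

  post <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$participant == id, c("participant", "trial", "f1", "f2")]
    rownames(tr) <- NULL
    check_track(tr, participant_ok = TRUE)
    discard_equilibration(tr, n_discard)
  }))
  screening <- screen_participants(post, max_failed_fraction)

  summaries <- list()
  series <- list()
  for (id in ids) {
    tr <- post[post$participant == id, , drop = FALSE]
    scr <- screening$summary[screening$summary$participant == id, ]
    n_implausible <- sum((!is.na(tr$f1) & (tr$f1 < F1_BOUNDS[1L] | tr$f1 > F1_BOUNDS[2L])) |
                         (!is.na(tr$f2) & (tr$f2 < F2_BOUNDS[1L] | tr$f2 > F2_BOUNDS[2L])))
    row <- data.frame(participant = id,
                      adaptation_hz = NA_real_, aftereffect_hz = NA_real_,
                      adaptation_pct = NA_real_, aftereffect_pct = NA_real_,
                      n_failed_tracks = scr$n_failed,
                      n_interpolated = NA_integer_,
                      n_implausible = n_implausible,
                      excluded = scr$excluded)
    if (!scr$excluded) {
      tr <- interpolate_missing(tr, max_gap)
      row$n_interpolated <- sum(attr(tr, "n_interpolated"))
      if (smooth) {
        for (col in c("f1", "f2")) {
          ok <- !is.na(tr[[col]])
          if (sum(ok) >= span)
            tr[[col]][ok] <- robust_smooth(tr[[col]][ok], span = span,
                                           iterations = smooth_iterations,
                                           x = tr$trial[ok])
        }
      }
      cs <- compensation_series(tr, baseline_window, inverse_alteration)
      summ <- summarize_participant(cs, hold_window, end_window)
      row[names(summ)] <- summ
      series[[id]] <- data.frame(participant = id, cs)
    }
    summaries[[id]] <- row
  }
  out <- list(summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
              series = if (length(series))
                do.call(rbind, c(series, list(make.row.names = FALSE))) else NULL,
              screening = screening)
  class(out) <- "aaf_formant_results"
  out
}

#' @export
print.aaf_formant_results <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("Formant pipeline: %d participants (%d excluded)\n",
              nrow(s), sum(s$excluded)))
  kept <- s[!s$excluded, ]
  if (nrow(kept)) {
    cat(sprintf("  adaptation:  median %.1f Hz (%.1f%%), range %.1f to %.1f Hz\n",
                stats::median(kept$adaptation_hz), stats::median(kept$adaptation_pct),
                min(kept$adaptation_hz), max(kept$adaptation_hz)))
    cat(sprintf("  aftereffect: median %.1f Hz (%.1f%%), range %.1f to %.1f Hz\n",
                stats::median(kept$aftereffect_hz), stats::median(kept$aftereffect_pct),
                min(kept$aftereffect_hz), max(kept$aftereffect_hz)))
  }
  invisible(x)
}

#' Read or write per-trial formant tables
#'
#' On-disk format: CSV with columns `participant,trial,f1_hz,f2_hz,valid`;
#' invalid trials (failed formant tracks) carry `valid = 0` and are read as
#' missing.
#'
#' @param tracks Data frame with `participant`, `trial`, `f1`, `f2`.
#' @param path File path.
#' @return `read_formant_tracks` returns the in-memory track table;
#'   `write_formant_tracks` returns `path` invisibly.
#' @export
read_formant_tracks <- function(path) {
  d <- utils::read.csv(path)
  need <- c("participant", "trial", "f1_hz", "f2_hz", "valid")
  if (!all(need %in% names(d)))
    abort(sprintf("formant CSV must have columns %s", paste(need, collapse = ",")),
          "adaptaaf_invalid_config")
  bad <- !as.logical(d$valid) | is.na(d$valid)
  data.frame(participant = d$participant, trial = d$trial,
             f1 = ifelse(bad, NA_real_, d$f1_hz),
             f2 = ifelse(bad, NA_real_, d$f2_hz))
}

#' @rdname read_formant_tracks
#' @export
write_formant_tracks <- function(tracks, path) {
  valid <- as.integer(!(is.na(tracks$f1) | is.na(tracks$f2)))
  out <- data.frame(participant = tracks$participant, trial = tracks$trial,
                    f1_hz = tracks$f1, f2_hz = tracks$f2, valid = valid)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
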