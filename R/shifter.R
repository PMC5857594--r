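# Offline formant shifter: frame-based LPC analysis, pole-angle modification
# for F1/F2, residual-excited resynthesis with overlap-add. Mirrors the
# analysis-modify-resynthesis chain of the real-time feedback alteration
# device, minus the latency constraint: 400-sample analysis buffers advanced in
# small hops at an 11.025 kHz sampling rate, LPC order 12. Also provides a
# source-filter vowel synthesizer and an LPC formant measurer for round-trip
# evaluation.

#' Audio buffer
#'
#' @param samples Finite numeric samples, nominally in \[-1, 1\].
#' @param rate Sampling rate in Hz (default 11025, the alteration device's
#'   rate).
#' @return List of class `audio_buffer` with `samples` and `rate`.
#' @export
audio_buffer <- function(samples, rate = 11025) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    abort("samples must be finite numbers", "adaptaaf_invalid_config")
  if (!is_number(rate) || rate <= 0)
    abort("rate must be positive", "adaptaaf_invalid_config")
  structure(list(samples = as.numeric(samples), rate = rate), class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("Audio buffer: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Shifter configuration
#'
#' @param lpc_order LPC model order (default 12, suited to an 11.025 kHz
#'   rate).
#' @param hop Frame advance in samples (default 32, the device's frame hop).
#' @param buffer_len Analysis buffer length in samples (default 400).
#' @param bw_cap Maximum bandwidth (Hz) for a pole pair to count as a formant
#'   candidate (default 400).
#' @return List of class `shifter_config`.
#' @export
shifter_config <- function(lpc_order = 12L, hop = 32L, buffer_len = 400L,
                           bw_cap = 400) {
  if (!is_count(lpc_order, 2) || !is_count(hop) || !is_count(buffer_len))
    abort("lpc_order, hop and buffer_len must be positive whole numbers",
          "adaptaaf_invalid_config")
  if (lpc_order >= buffer_len)
    abort("lpc_order must be smaller than buffer_len", "adaptaaf_invalid_config")
  if (hop > buffer_len)
    abort("hop cannot exceed buffer_len", "adaptaaf_invalid_config")
  structure(list(lpc_order = lpc_order, hop = hop, buffer_len = buffer_len,
                 bw_cap = bw_cap), class = "shifter_config")
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# autocorrelation-method LPC; returns the prediction polynomial
# A = c(1, -a_1, ..., -a_p) or NULL for degenerate (near-silent) frames
lpc_coefficients <- function(frame, order) {
  n <- length(frame)
  r <- vapply(0:order, function(k) sum(frame[1:(n - k)] * frame[(1 + k):n]),
              numeric(1L))
  if (r[1L] <= 1e-12) return(NULL)
  # white-noise floor: conditions the Toeplitz solve and shrinks the spurious
  # near-unit-circle poles that degenerate inputs (e.g. pure tones) produce
  r[1L] <- r[1L] * (1 + 1e-3)
  a <- tryCatch(solve(stats::toeplitz(r[1:order]), r[2:(order + 1L)]),
                error = function(e) NULL)
  if (is.null(a) || anyNA(a) || any(!is.finite(a))) return(NULL)
  c(1, -a)
}

# roots of the LPC polynomial in z (poles of 1/A)
lpc_poles <- function(A) polyroot(rev(A))

pole_frequency <- function(z, rate) Arg(z) * rate / (2 * pi)
pole_bandwidth <- function(z, rate) -log(pmin(Mod(z), 1 - 1e-12)) * rate / pi

# formant-candidate poles: positive-frequency complex poles, plausible band,
# bandwidth below cap, sorted by frequency
formant_poles <- function(A, rate, bw_cap, fmin = 90) {
  z <- lpc_poles(A)
  z <- z[Im(z) > 1e-8]
  f <- pole_frequency(z, rate)
  bw <- pole_bandwidth(z, rate)
  keep <- f > fmin & f < rate / 2 - fmin & bw < bw_cap
  z <- z[keep]
  z[order(pole_frequency(z, rate))]
}

#' Synthesize a steady vowel
#'
#' Source-filter synthesis: an impulse-train glottal source at `f0` filtered
#' through cascaded second-order resonators, one per formant, then
#' peak-normalized to 0.9. Intended as a controlled fixture for evaluating the
#' formant shifter and measurer.
#'
#' @param f0 Fundamental frequency, Hz (< rate/2).
#' @param formants List of `c(center_hz, bandwidth_hz)` pairs (all centers
#'   below the Nyquist frequency).
#' @param duration Duration in seconds (> 0).
#' @param rate Sampling rate, Hz.
#' @return An [audio_buffer()].
#' @examples
#' v <- synthesize_vowel(120, list(c(500, 80), c(1500, 100)), 0.3)
#' measure_formants(v)
#' @export
synthesize_vowel <- function(f0 = 120, formants = list(c(500, 80), c(1500, 100)),
                             duration = 0.5, rate = 11025) {
  if (!is_number(duration) || duration <= 0)
    abort("duration must be positive", "adaptaaf_invalid_config")
  if (!is_number(f0) || f0 <= 0 || f0 >= rate / 2)
    abort("f0 must be positive and below the Nyquist frequency", "adaptaaf_invalid_config")
  n <- round(duration * rate)
  if (n < 1L) abort("duration too short for one sample", "adaptaaf_invalid_config")
  x <- numeric(n)
  x[seq(1L, n, by = max(1L, round(rate / f0)))] <- 1
  for (fm in formants) {
    if (length(fm) != 2L || !is.finite(fm[1L]) || !is.finite(fm[2L]) ||
        fm[1L] <= 0 || fm[2L] <= 0)
      abort("each formant must be c(center_hz, bandwidth_hz), both positive",
            "adaptaaf_invalid_config")
    if (fm[1L] >= rate / 2)
      abort("formant center above the Nyquist frequency", "adaptaaf_invalid_config")
    r <- exp(-pi * fm[2L] / rate)
    a <- c(1, -2 * r * cos(2 * pi * fm[1L] / rate), r^2)
    x <- as.numeric(signal::filter(1, a, x))
  }
  audio_buffer(0.9 * x / max(abs(x)), rate)
}

#' Measure average F1/F2 of a buffer
#'
#' Frames the signal, fits an LPC model per frame (frames with enough energy
#' only), extracts formant-candidate poles (bandwidth below `bw_cap`), and
#' averages the two lowest candidate frequencies over frames. When no frame
#' yields two stable candidates — silence, noise without formant structure —
#' the measurement fails and `c(NA, NA)` is returned with a warning, modelling
#' a failed formant track.
#'
#' @param audio An [audio_buffer()].
#' @param lpc_order LPC order (default 12).
#' @param frame_len,hop Analysis framing in samples.
#' @param bw_cap Formant-candidate bandwidth cap, Hz.
#' @return Named numeric `c(f1 = , f2 = )`, Hz (NA on failure), with attribute
#'   `n_frames_used`.
#' @export
measure_formants <- function(audio, lpc_order = 12L, frame_len = 400L,
                             hop = 200L, bw_cap = 400) {
  if (!inherits(audio, "audio_buffer"))
    abort("audio must be an audio_buffer", "adaptaaf_invalid_config")
  x <- audio$samples
  if (length(x) < frame_len)
    abort("audio shorter than one analysis frame", "adaptaaf_invalid_config")
  w <- hamming_window(frame_len)
  starts <- seq(1L, length(x) - frame_len + 1L, by = hop)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + frame_len - 1L)]^2)),
                numeric(1L))
  voiced <- rms >= max(0.05 * max(rms), 1e-6)
  est <- matrix(NA_real_, length(starts), 2L)
  for (k in which(voiced)) {
    s <- starts[k]
    A <- lpc_coefficients(x[s:(s + frame_len - 1L)] * w, lpc_order)
    if (is.null(A)) next
    z <- formant_poles(A, audio$rate, bw_cap)
    if (length(z) >= 2L)
      est[k, ] <- pole_frequency(z[1:2], audio$rate)
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) {
    warning("formant measurement failed: no frame produced two stable formant poles")
    return(structure(c(f1 = NA_real_, f2 = NA_real_), n_frames_used = 0L))
  }
  out <- colMeans(est[ok, , drop = FALSE])
  structure(c(f1 = min(out), f2 = max(out)), n_frames_used = sum(ok))
}

#' Shift formants by rotating LPC poles
#'
#' Per analysis frame: fit an LPC model, identify the two lowest-frequency
#' formant-candidate pole pairs (F1 and F2), rotate their angles by
#' `2*pi*shift/rate` with radii (bandwidths) preserved, and re-filter the
#' frame's prediction residual through the modified all-pole filter. Frames are
#' windowed, overlap-added and normalized; the output's overall level is
#' matched to the input (pole movement, especially of F1, otherwise changes
#' the spectral amplitude audibly). Frames without two formant candidates are
#' passed through unmodified with a warning.
#'
#' @param audio An [audio_buffer()] at least one buffer long.
#' @param shift Length-2 `c(f1_shift, f2_shift)` in Hz (the alteration applied
#'   to the feedback).
#' @param config A [shifter_config()].
#' @return An [audio_buffer()] of the same length and rate.
#' @export
shift_formants <- function(audio, shift, config = shifter_config()) {
  if (!inherits(audio, "audio_buffer"))
    abort("audio must be an audio_buffer", "adaptaaf_invalid_config")
  if (!inherits(config, "shifter_config"))
    abort("config must be a shifter_config", "adaptaaf_invalid_config")
  shift <- as_alteration(shift)
  x <- audio$samples
  n <- length(x)
  L <- config$buffer_len
  if (n < L)
    abort("audio shorter than the analysis buffer", "adaptaaf_invalid_config")

  w <- hann_window(L)
  out <- numeric(n)
  wsum <- numeric(n)
  dtheta <- 2 * pi * shift / audio$rate
  skipped <- 0L
  rms_all <- sqrt(mean(x^2))
  starts <- seq(1L, n - L + 1L, by = config$hop)
  for (s in starts) {
    span <- s:(s + L - 1L)
    frame <- x[span] * w
    newframe <- frame
    # low-energy frames (attack/decay, pauses) carry no usable formant
    # structure; pass them through like the device's amplitude gate
    A <- if (sqrt(mean(frame^2)) >= 0.02 * rms_all)
      lpc_coefficients(frame, config$lpc_order) else NULL
    if (!is.null(A)) {
      z <- lpc_poles(A)
      up <- z[Im(z) > 1e-8]
      f <- pole_frequency(up, audio$rate)
      bw <- pole_bandwidth(up, audio$rate)
      cand <- which(f > 90 & f < audio$rate / 2 - 90 & bw < config$bw_cap)
      cand <- cand[order(f[cand])]
      if (length(cand) >= 2L) {
        sel <- cand[1:2]
        theta_new <- Arg(up[sel]) + dtheta
        ok <- theta_new > 0.005 & theta_new < pi - 0.005
        up[sel[ok]] <- complex(modulus = Mod(up[sel[ok]]), argument = theta_new[ok])
        real_roots <- z[abs(Im(z)) <= 1e-8]
        A2 <- Re(pracma::Poly(c(up, Conj(up), real_roots)))
        residual <- as.numeric(signal::filter(A, 1, frame))
        newframe <- as.numeric(signal::filter(1, A2, residual))
        rin <- sqrt(mean(frame^2))
        rout <- sqrt(mean(newframe^2))
        if (rout > 0) newframe <- newframe * rin / rout
        # degenerate frames can ring after pole movement; keep the original
        if (!all(is.finite(newframe)) ||
            max(abs(newframe)) > 10 * max(abs(frame)))
          newframe <- frame
      } else skipped <- skipped + 1L
    } else skipped <- skipped + 1L
    out[span] <- out[span] + newframe * w
    wsum[span] <- wsum[span] + w^2
  }
  if (skipped > 0L)
    warning(sprintf("%d of %d frames had fewer than two formant poles and were passed through",
                    skipped, length(starts)))
  # samples near the edges accumulate almost no window weight; dividing by a
  # vanishing weight would amplify noise, so fall back to the input there
  covered <- wsum > 0.1 * max(wsum)
  out[covered] <- out[covered] / wsum[covered]
  out[!covered] <- x[!covered]
  rin <- sqrt(mean(x^2))
  rout <- sqrt(mean(out^2))
  if (rout > 0 && rin > 0) out <- out * rin / rout
  audio_buffer(out, audio$rate)
}

#' Read or write mono 16-bit PCM WAV files
#'
#' Minimal RIFF reader/writer for the shifter's file interface: mono 16-bit
#' PCM only; any other encoding or channel count is refused (never silently
#' resampled or mixed down).
#'
#' @param path File path.
#' @param audio An [audio_buffer()]; samples are clipped to \[-1, 1\] on
#'   write.
#' @return `read_wav` returns an [audio_buffer()]; `write_wav` returns `path`
#'   invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "RIFF")
    abort("not a RIFF/WAV file", "adaptaaf_invalid_input")
  readBin(con, "integer", 1L, size = 4L)
  if (rawToChar(readBin(con, "raw", 4L)) != "WAVE")
    abort("not a RIFF/WAV file", "adaptaaf_invalid_input")
  rate <- NULL; bits <- NULL; channels <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L)
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 1L, size = 2L)
      channels <- readBin(con, "integer", 1L, size = 2L)
      rate <- readBin(con, "integer", 1L, size = 4L)
      readBin(con, "integer", 1L, size = 4L)  # byte rate
      readBin(con, "integer", 1L, size = 2L)  # block align
      bits <- readBin(con, "integer", 1L, size = 2L)
      extra <- size - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (tag == "data") {
      samples <- readBin(con, "integer", size / 2L, size = 2L, signed = TRUE)
      break
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(fmt) || is.null(samples))
    abort("malformed WAV file", "adaptaaf_invalid_input")
  if (fmt != 1L || bits != 16L)
    abort("only 16-bit PCM WAV is supported", "adaptaaf_invalid_input")
  if (channels != 1L)
    abort("only mono WAV is supported", "adaptaaf_invalid_input")
  audio_buffer(samples / 32767, rate)
}

#' @rdname read_wav
#' @export
write_wav <- function(audio, path) {
  if (!inherits(audio, "audio_buffer"))
    abort("audio must be an audio_buffer", "adaptaaf_invalid_config")
  s <- as.integer(round(pmin(pmax(audio$samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4L)
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L)
  writeBin(c(1L, 1L), con, size = 2L)                   # PCM, mono
  writeBin(as.integer(audio$rate), con, size = 4L)
  writeBin(as.integer(audio$rate * 2L), con, size = 4L) # byte rate
  writeBin(c(2L, 16L), con, size = 2L)                  # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L)
  writeBin(s, con, size = 2L)
  invisible(path)
}
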