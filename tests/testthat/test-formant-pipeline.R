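test_that("equilibration discard drops leading trials and keeps indices", {
  tr <- data.frame(trial = 1:100, f1 = 500, f2 = 1800)
  out <- discard_equilibration(tr, 5)
  expect_equal(nrow(out), 95)
  expect_equal(out$trial[1], 6)
  expect_identical(discard_equilibration(tr, 0), tr)
  expect_error(discard_equilibration(tr, 100), class = "adaptaaf_invalid_config")
})

test_that("bounded gaps are linearly interpolated, long gaps counted, edges filled nearest", {
  tr <- data.frame(trial = 1:20, f1 = 1000, f2 = 2000)
  tr$f1[10] <- 500; tr$f1[13] <- 530; tr$f1[11:12] <- NA
  out <- interpolate_missing(tr, 4)
  expect_equal(out$f1[11:12], c(510, 520))
  expect_equal(attr(out, "n_interpolated")[["f1"]], 2L)

  # run of 5 consecutive missing with max_gap 4 stays missing and is counted
  tr5 <- data.frame(trial = 1:20, f1 = c(rep(500, 7), rep(NA, 5), rep(520, 8)), f2 = 2000)
  out5 <- interpolate_missing(tr5, 4)
  expect_equal(sum(is.na(out5$f1)), 5L)
  expect_equal(attr(out5, "n_unfilled")[["f1"]], 5L)

  # leading/trailing runs take the nearest valid value
  tre <- data.frame(trial = 1:10, f1 = c(NA, NA, 500, NA, 510, rep(520, 5)), f2 = 2000)
  oute <- interpolate_missing(tre, 4)
  expect_equal(oute$f1[1:2], c(500, 500))
  expect_equal(oute$f1[4], 505)

  # complete track is unchanged; fully missing formant is unusable
  full <- data.frame(trial = 1:10, f1 = rnorm(10, 500), f2 = rnorm(10, 1800))
  expect_equal(interpolate_missing(full, 4)$f1, full$f1)
  allna <- data.frame(trial = 1:10, f1 = NA_real_, f2 = 2000)
  expect_error(interpolate_missing(allna, 4), class = "adaptaaf_unusable_track")
})

test_that("robust smoother reproduces constants and lines and rejects spikes", {
  expect_equal(robust_smooth(rep(5, 12)), rep(5, 12))
  x <- 1:30
  line <- 2.5 * x + 7
  expect_equal(robust_smooth(line), line, tolerance = 1e-10)
  # isolated spike far beyond the robust scale is zero-weighted: the smoothed
  # value at the spike returns to the underlying line
  spiked <- line
  spiked[14] <- spiked[14] + 120
  out <- robust_smooth(spiked)
  expect_lt(abs(out[14] - line[14]), 1)
  expect_error(robust_smooth(line, span = 4), class = "adaptaaf_invalid_config")
  expect_error(robust_smooth(line[1:3], span = 5), class = "adaptaaf_invalid_config")
  expect_error(robust_smooth(c(1, NA, 3, 4, 5)), class = "adaptaaf_invalid_config")
})

test_that("scalar projection matches the worked values and is linear", {
  b1 <- 500; b2 <- 1800
  expect_equal(round(scalar_projection(b1 + 150, b2 - 300, b1, b2), 2), 335.41)
  expect_equal(scalar_projection(b1, b2, b1, b2), 0)
  # orthogonal formant change projects to zero
  expect_equal(scalar_projection(b1 + 300, b2 + 150, b1, b2), 0)
  expect_equal(round(scalar_projection(b1 + 75, b2 - 150, b1, b2), 2), 167.71)
  # linearity in the formant change
  set.seed(1)
  for (i in 1:20) {
    d1 <- rnorm(2, 0, 80); d2 <- rnorm(2, 0, 80); a <- rnorm(1)
    expect_equal(
      scalar_projection(b1 + d1[1] + a * d2[1], b2 + d1[2] + a * d2[2], b1, b2),
      scalar_projection(b1 + d1[1], b2 + d1[2], b1, b2) +
        a * scalar_projection(b1 + d2[1], b2 + d2[2], b1, b2))
  }
  # the inverse-alteration vector itself projects to the alteration magnitude
  v <- c(150, -300)
  expect_equal(scalar_projection(b1 + v[1], b2 + v[2], b1, b2, v), alteration_magnitude(v))
  expect_true(is.na(scalar_projection(NA, b2, b1, b2)))
  expect_error(scalar_projection(b1, b2, b1, b2, c(0, 0)), class = "adaptaaf_invalid_config")
})

test_that("projection never exceeds the formant-change vector length", {
  set.seed(2)
  for (i in 1:50) {
    d <- rnorm(2, 0, 100)
    cval <- scalar_projection(500 + d[1], 1800 + d[2], 500, 1800)
    expect_lte(abs(cval), sqrt(sum(d^2)) + 1e-9)
  }
})

test_that("windowed medians give adaptation and aftereffect in Hz and percent", {
  zero <- summarize_participant(fixed_series(0, 0))
  expect_equal(unlist(zero), c(adaptation_hz = 0, aftereffect_hz = 0,
                               adaptation_pct = 0, aftereffect_pct = 0))
  perfect <- summarize_participant(fixed_series(alteration_magnitude(c(-150, 300)),
                                                alteration_magnitude(c(-150, 300))))
  expect_equal(round(perfect$adaptation_hz, 2), 335.41)
  expect_equal(perfect$adaptation_pct, 100)
  # the reported median/maximum adaptation and minimum aftereffect convert to
  # the printed percentages at one decimal
  rep78 <- summarize_participant(fixed_series(78, -26))
  expect_equal(round(rep78$adaptation_pct, 1), 23.3)
  expect_equal(round(rep78$aftereffect_pct, 1), -7.8)
  expect_equal(round(summarize_participant(fixed_series(137, 0))$adaptation_pct, 1), 40.8)
  expect_error(summarize_participant(fixed_series(0, 0), hold_window = 200:220),
               class = "adaptaaf_invalid_config")
})

test_that("adaptation is invariant to permuting trials within the hold window", {
  set.seed(3)
  cs <- fixed_series(0, 0)
  cs$c <- rnorm(100, 40, 25)
  base <- summarize_participant(cs)
  perm <- cs
  perm$c[61:80] <- sample(perm$c[61:80])
  expect_equal(summarize_participant(perm)$adaptation_hz, base$adaptation_hz)
})

test_that("participants with excessive tracking failure are screened out", {
  mk <- function(id, n_missing) {
    f1 <- rep(500, 95); f1[seq_len(n_missing)] <- NA
    data.frame(participant = id, trial = 6:100, f1 = f1, f2 = 1800)
  }
  tracks <- rbind(mk("bad", 60), mk("good", 0), mk("edge", 47))  # 47/95 < 0.5 < 60/95
  scr <- screen_participants(tracks)
  expect_equal(scr$excluded, "bad")
  expect_setequal(scr$kept, c("good", "edge"))
  # exactly at the threshold the participant is kept (strict inequality)
  half <- mk("half", 10); half$f1[1:5] <- NA  # rebuild with exactly half missing
  half <- data.frame(participant = "half", trial = 1:10,
                     f1 = c(rep(NA, 5), rep(500, 5)), f2 = 1800)
  expect_equal(screen_participants(half)$kept, "half")
})

test_that("noiseless constant-compensation speaker recovers rho * 335.41 exactly", {
  for (rho in c(0, 0.25, 0.37, 1)) {
    tr <- constant_compensation_track(rho)
    s <- process_formants(tr)$summaries
    expect_lt(abs(s$adaptation_hz - rho * alteration_magnitude(c(-150, 300))), 0.01)
    expect_lt(abs(s$aftereffect_hz - rho * alteration_magnitude(c(-150, 300))), 0.01)
  }
})

test_that("summaries from raw and smoothed series agree to within median noise", {
  sched <- build_schedule()
  set.seed(11)
  difs <- c()
  for (i in 1:15) {
    sp <- speaker_params(acuity = runif(1, .2, .9), noise_sd = 10, failure_rate = 0)
    tr <- simulate_speaker(sp, sched)
    tr$participant <- "P1"
    a <- process_formants(tr, smooth = TRUE)$summaries
    b <- process_formants(tr, smooth = FALSE)$summaries
    difs <- c(difs, abs(a$adaptation_hz - b$adaptation_hz),
              abs(a$aftereffect_hz - b$aftereffect_hz))
  }
  expect_lt(mean(difs), 4)
  expect_lt(max(difs), 12)
})

test_that("full pipeline handles missing data, screening and reporting together", {
  sched <- build_schedule()
  set.seed(21)
  good <- simulate_speaker(speaker_params(acuity = 0.8, failure_rate = 0.02), sched)
  bad <- simulate_speaker(speaker_params(acuity = 0.4, failure_rate = 0.7), sched)
  tracks <- rbind(data.frame(participant = "good", good),
                  data.frame(participant = "bad", bad))
  res <- process_formants(tracks)
  s <- res$summaries
  expect_true(s$excluded[s$participant == "bad"])
  expect_false(s$excluded[s$participant == "good"])
  expect_true(is.na(s$adaptation_hz[s$participant == "bad"]))
  expect_true(is.finite(s$adaptation_hz[s$participant == "good"]))
  expect_true(all(res$series$participant == "good"))
  expect_equal(s$adaptation_pct, 100 * s$adaptation_hz / alteration_magnitude(c(-150, 300)))
})

test_that("formant trial tables round-trip through the CSV format", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- constant_compensation_track(0.3)
  tr$f1[c(7, 8)] <- NA
  tr$f2[c(7, 8)] <- NA
  write_formant_tracks(tr, path)
  back <- read_formant_tracks(path)
  expect_equal(back$f1, tr$f1)
  expect_equal(back$f2, tr$f2)
  expect_equal(back$trial, tr$trial)
})
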