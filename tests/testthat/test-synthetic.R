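test_that("speaker dynamics have the closed-form fixed point", {
  sched <- build_schedule()
  # zero gain: no compensation on any trial
  tr0 <- simulate_speaker(speaker_params(gain = 0, anchor = 0.2, noise_sd = 0,
                                         dead_zone_hz = 0, failure_rate = 0), sched)
  expect_true(all(attr(tr0, "compensation") == 0))
  expect_equal(compensation_series(tr0)$c, rep(0, 100))

  # no anchor, no dead zone: full compensation of the inverse alteration
  trf <- simulate_speaker(speaker_params(gain = 0.3, anchor = 0, noise_sd = 0,
                                         dead_zone_hz = 0, failure_rate = 0), sched)
  cs <- compensation_series(trf)
  expect_lt(abs(median(cs$c[cs$trial %in% 61:80]) - alteration_magnitude(c(-150, 300))),
            0.05)

  # anchored: asymptote at gain/(gain + anchor) of the full alteration,
  # long-run simulation within 1% of the closed form
  long <- build_schedule(n_hold = 10000)
  trl <- simulate_speaker(speaker_params(gain = 0.1, anchor = 0.2, noise_sd = 0,
                                         dead_zone_hz = 0, failure_rate = 0), long)
  csl <- compensation_series(trl)
  target <- 0.1 / 0.3 * alteration_magnitude(c(-150, 300))
  final <- csl$c[csl$trial == 20 + 20 + 10000]
  expect_lt(abs(final - target) / target, 0.01)

  expect_error(speaker_params(gain = 0.7, anchor = 0.4),
               class = "adaptaaf_divergent_speaker")
})

test_that("speaker simulation is seed-reproducible and respects the dead zone", {
  sched <- build_schedule()
  sp <- speaker_params(acuity = 0.6)
  a <- simulate_speaker(sp, sched, seed = 3)
  b <- simulate_speaker(sp, sched, seed = 3)
  expect_identical(a, b)
  # a dead zone wider than the alteration suppresses all correction
  wide <- speaker_params(gain = 0.3, anchor = 0, dead_zone_hz = 400,
                         noise_sd = 0, failure_rate = 0)
  trw <- simulate_speaker(wide, sched)
  expect_true(all(attr(trw, "compensation") == 0))
})

test_that("observer percent-correct has the logistic shape and limits", {
  obs <- observer_params(2, slope = 0.4, lapse = 0.05)
  expect_equal(observer_p_correct(obs, 2), 0.5 + (0.5 - 0.05) / 2)
  expect_equal(observer_p_correct(obs, 1e9), 1 - 0.05, tolerance = 1e-6)
  expect_equal(observer_p_correct(obs, 1e-9), 0.5, tolerance = 1e-6)
  d <- exp(seq(-4, 4, length.out = 50))
  expect_true(all(diff(observer_p_correct(obs, d)) >= 0))
  expect_error(observer_p_correct(obs, 0), class = "adaptaaf_invalid_input")
  expect_error(observer_params(2, lapse = 0.5), class = "adaptaaf_invalid_config")
})

test_that("melody pairs satisfy their construction invariants", {
  major <- c(0, 2, 4, 5, 7, 9, 11)
  in_key <- function(notes, tonic) all(((notes - tonic) %% 12) %in% major)
  for (s in 1:40) {
    n <- sample(5:13, 1)
    type <- sample(c("same", "different"), 1)
    transposed <- sample(c(TRUE, FALSE), 1)
    mp <- generate_melody_pair(n, type, transposed, seed = s)
    expect_length(mp$notes_b, length(mp$notes_a))
    expect_true(in_key(mp$notes_a, mp$tonic))
    # contour (signs of successive intervals) always preserved
    expect_equal(sign(diff(mp$notes_b)), sign(diff(mp$notes_a)))
    if (type == "same") {
      expect_equal(mp$notes_b, mp$notes_a + if (transposed) 4L else 0L)
      expect_true(is.na(mp$changed_index))
    } else {
      base <- mp$notes_a + if (transposed) 4L else 0L
      diffs <- which(mp$notes_b != base)
      expect_equal(diffs, mp$changed_index)
      delta <- mp$notes_b[diffs] - base[diffs]
      if (transposed) {
        # 1-semitone change to a pitch outside the transposed key
        expect_equal(abs(delta), 1)
        expect_false(in_key(mp$notes_b[diffs], mp$tonic + 4))
      } else {
        # up to 5 semitones, staying in key
        expect_lte(abs(delta), 5)
        expect_true(in_key(mp$notes_b, mp$tonic))
      }
    }
  }
  expect_error(generate_melody_pair(3, "same"), class = "adaptaaf_invalid_config")
  a <- generate_melody_pair(9, "different", seed = 11)
  b <- generate_melody_pair(9, "different", seed = 11)
  expect_identical(a, b)
})

test_that("simulated RT tables have the requested structure", {
  tab <- simulate_rt_table(16, 500, 20, 30, sd = 0, error_rate = 0, seed = 4)
  expect_equal(nrow(tab), 48)
  expect_equal(sort(unique(tab$condition)), c("congruent", "incongruent", "neutral"))
  expect_equal(conflict_scores(tab)$interference_ms, -50)
  flat <- simulate_rt_table(16, 500, 0, 0, sd = 0, error_rate = 0, seed = 4)
  expect_equal(conflict_scores(flat)$interference_ms, 0)
})

test_that("cohort bundles are bit-identical under a fixed seed", {
  a <- generate_cohort(cohort_spec(n = 6, seed = 99))
  b <- generate_cohort(cohort_spec(n = 6, seed = 99))
  expect_identical(a$formants, b$formants)
  expect_identical(a$staircase, b$staircase)
  expect_identical(a$melody, b$melody)
  expect_identical(a$rt_trials, b$rt_trials)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_error(generate_cohort(cohort_spec(n = 1)), class = "adaptaaf_invalid_config")
})

test_that("zero coupling decouples measured thresholds from adaptation", {
  rs <- c()
  for (s in 1:5) {
    spec <- cohort_spec(n = 60, seed = 200 + s, gain_coupling = 0,
                        threshold_coupling = c(pitch = 0, loudness = 0),
                        melody_coupling = 0, dead_zone_scale = 0)
    m <- analyze_cohort(generate_cohort(spec))
    rs <- c(rs, cor(m$adaptation_hz, m$pitch_threshold),
            cor(m$adaptation_hz, m$loudness_threshold))
  }
  expect_lt(mean(abs(rs)), 0.2)
})

test_that("true interference effects are independent of the adaptation gain", {
  rs <- c()
  for (s in 1:6) {
    gt <- generate_cohort(cohort_spec(n = 200, seed = 300 + s))$ground_truth
    rs <- c(rs, cor(gt$interference_stroop_true, gt$gain),
            cor(gt$interference_simon_true, gt$gain),
            cor(gt$interference_flanker_true, gt$gain))
  }
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("the analysis pipeline recovers the acuity-coupled structure", {
  acuity_preds <- c("loudness_threshold", "pitch_threshold", "melody_pct")
  noise_preds <- c("interference_stroop", "interference_simon", "interference_flanker")
  kept_acuity <- 0L
  dropped_each <- setNames(integer(3), noise_preds)
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    bundle <- generate_cohort(cohort_spec(n = 200, seed = 400 + s))
    m <- analyze_cohort(bundle)
    # measured adaptation tracks the latent acuity strongly
    gt <- bundle$ground_truth[match(m$participant, bundle$ground_truth$participant), ]
    expect_gt(cor(m$adaptation_hz, gt$acuity), 0.5)
    fin <- adaptation_model(m)$elimination$final$predictors
    kept_acuity <- kept_acuity + all(acuity_preds %in% fin)
    for (p in noise_preds) dropped_each[p] <- dropped_each[p] + !(p %in% fin)
  }
  expect_equal(kept_acuity, n_seeds)
  # each null predictor is dropped at roughly 1 - p_remove per seed
  expect_true(all(dropped_each >= 8))
})

test_that("cohort bundles round-trip to a directory of CSV files", {
  dir <- withr::local_tempdir()
  bundle <- generate_cohort(cohort_spec(n = 4, seed = 5))
  write_cohort(bundle, dir)
  files <- c("formants.csv", "staircase_runs.csv", "melody.csv",
             "rt_trials.csv", "ground_truth.csv", "manifest.json")
  expect_true(all(file.exists(file.path(dir, files))))
  back <- read_formant_tracks(file.path(dir, "formants.csv"))
  expect_equal(back$f1, bundle$formants$f1)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 5)
  expect_equal(manifest$n, 4)
})
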