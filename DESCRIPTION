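Package: adaptaaf
Title: Sensorimotor Adaptation to Altered Auditory Feedback: Simulation and
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sensorimotor adaptation of vowel production
    under altered auditory feedback. Builds the four-phase formant perturbation
    schedule, preprocesses per-trial F1/F2 formant tracks (equilibration
    discard, bounded-gap interpolation, robust local-regression smoothing) and
    computes the scalar-projection compensation statistic with windowed-median
    adaptation and aftereffect summaries. Includes a 2-down/1-up transformed
    staircase engine with geometric-mean threshold extraction for pitch and
    loudness discrimination, conflict-task (Stroop, Simon, Flanker) reaction
    time scoring, predictor screening with automatic backward-elimination
    multiple regression on standardized scores, a synthetic-data generator
    (adapting speakers, psychometric observers, reaction-time tables, melody
    stimuli, linked cohorts with ground truth), and an offline LPC pole-shifting
    formant modifier with vowel synthesis for round-trip evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
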