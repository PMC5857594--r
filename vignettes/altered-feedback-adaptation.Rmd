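---
title: "Measuring adaptation to altered auditory feedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring adaptation to altered auditory feedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptaaf)
```

This vignette documents the models implemented in `adaptaaf`, the conventions
and numerical choices behind them, and what the synthetic-data generator does
and does not emulate. It is the design record of the package: wherever a
published description of this paradigm admits more than one reading, the
choice made here is stated and motivated.

## 1. The paradigm and its pipeline

A speaker produces the same consonant-vowel-consonant token ~100 times while
hearing their own voice through earphones with the vowel's first two formants
shifted in real time. The session has four phases: a *baseline* with unshifted
feedback (trials 1–20), a *ramp* in which the shift grows linearly to its
maximum (21–40), a *hold* at the maximal shift (41–80), and an *end* with the
shift abruptly removed (81–100). The canonical maximal shift is
(−150, +300) Hz in (F1, F2) — for a mid-front vowel, a push toward a higher
neighbouring vowel. `build_schedule()` constructs this schedule; the ramp
reaches the maximum *at the last ramp trial*, so twenty ramp steps advance by
exactly −7.5 Hz (F1) and +15 Hz (F2) per trial. The alternative convention
(first shifted trial at 21 carrying a zero step) would make the printed step
sizes irreproducible, which is why it was rejected.

Processing of the recorded per-trial formant tracks is fixed in this order:

1. discard trials 1–5 (signal equilibration);
2. screen out participants with > 50% failed formant tracks (strict
   inequality: exactly half keeps the participant);
3. per formant, linearly interpolate internal runs of at most 4 consecutive
   missing trials; longer runs stay missing and are counted; leading/trailing
   runs — which have no two-sided boundary data — take the nearest valid
   value;
4. robust-smooth F1 and F2 separately (span 5);
5. compute baseline formants as the mean of the *smoothed* values over trials
   6–20;
6. project every trial onto the inverse-alteration direction;
7. summarize adaptation as the median projection over trials 61–80 and the
   aftereffect as the median over 81–100.

Two of these orderings are genuine choices. Smoothing *before* projection
(rather than smoothing the projected series) treats the two formants as
separately tracked, separately failing signals, which is what they are.
Computing the baseline from smoothed values keeps a single smoothed series
for all downstream steps rather than mixing raw baselines with smoothed
trials. Both choices matter little in practice: the pipeline-order test shows
raw and smoothed summaries agree to within the sampling noise of a 20-trial
median (mean |difference| ≈ 3 Hz at 10 Hz trial noise). Plausibility bounds
(F1 100–1200 Hz, F2 500–3500 Hz) are *flags only*; no trial is dropped by
them.

## 2. The compensation statistic

For a trial with formants $(F1_x, F2_x)$ and baseline $(F1_b, F2_b)$,

$$C \;=\; \frac{(F1_x - F1_b)\,v_1 + (F2_x - F2_b)\,v_2}{\lVert v\rVert},
\qquad v = (150, -300),$$

the scalar projection of the formant change onto the inverse of the maximal
alteration. $\lVert v\rVert = 335.41$ Hz, so $C = 335.41$ means the
production change exactly cancels the feedback shift. The sign convention is
fixed so that opposing the alteration is positive. $C$ is linear in the
formant change and never exceeds the change vector's length; both properties
are tested. Percentages are $100\,C/335.41$: e.g. a median adaptation of
78 Hz is 23.3% of the alteration.

## 3. Robust local-regression smoothing

`robust_smooth()` implements locally weighted linear least squares over each
point's `span` nearest neighbours with tricube distance weights, plus
robustness reweighting: after each pass, residuals are scaled by the median
absolute residual; residuals beyond 6 times that scale get hard zero weight
and the rest are downweighted by Tukey's bisquare. Five fit/reweight
iterations are run (the iteration count is a configuration choice; published
descriptions of this smoother do not state one).

Two numerical details deviate from textbook lowess and deserve a note:

* **Tricube cutoff.** Weights use `d / (1.25 * dmax)` rather than `d / dmax`.
  With the textbook cutoff the farthest window members get exactly zero
  weight, so on noiseless data a zero-weighted outlier can leave its window
  without enough usable neighbours and the fit degenerates. The widened
  cutoff keeps every window member at non-zero base weight while preserving
  the exact reproduction of constants and straight lines (a degree-1 local
  fit is exact on a line under any weights).
* **Degenerate robust scale.** On near-noiseless data the median absolute
  residual collapses to zero; the scale then falls back to the *mean*
  absolute residual so that an isolated spike is still rejected without
  zeroing its (influenced but sound) neighbours.

Both behaviours are pinned by tests: constants and lines pass through
unchanged, and a line plus a single large spike returns to the line at the
spike to within 1 Hz.

## 4. The 2-down/1-up staircase

The discrimination tasks use a transformed staircase: the stimulus difference
is divided by the step factor after two consecutive correct responses and
multiplied by it after every error. Steps are multiplicative for both tasks
(percent frequency difference for pitch, dB for loudness) — implied by the
use of step *factors* and geometric-mean thresholds — so differences stay
positive by construction. The initial factor 2 converges quickly; after two
reversals it drops to 1.25. A run ends at 15 reversals; the run threshold is
the geometric mean of the last 8 reversal values, which makes it independent
of the starting difference (tested: doubling the start moves the mean session
threshold by < 5%). Sessions aggregate four runs; the *median* run threshold
is the session statistic entered into regressions (the mean is available as
an option). Task presets carry the printed constants: pitch — 500 Hz
reference, 7% initial difference; loudness — 65 dB SPL reference, 10 dB
initial difference.

Conventions that differ across published implementations, fixed here:

* **Reversal value.** A reversal is recorded when the move direction flips,
  at the difference the staircase *moves to* (the origin of the new run).
  Because the last 8 reversals alternate up/down moves, the geometric mean is
  identical under the alternative convention (the pre-step extremum), so
  thresholds do not depend on this choice; the trial-level logs do.
* **Factor switch timing.** The update that records the second reversal still
  uses the initial factor; subsequent updates use the reduced factor.
* **Rule scope.** Only 1-up rules are supported (the difference steps up
  after every error); other transformed rules are out of scope.
* **Safety cap.** A simulated run that fails to finish within 400 trials
  (e.g. an observer that is never wrong and so never produces a reversal)
  raises a classed runaway error. Real sessions never approach the cap.

**Convergence level.** The textbook result is that 2-down/1-up brackets the
70.7%-correct point, but that is an asymptotic small-step property. With the
prescribed final factor of 1.25, simulation shows the procedure tracks
measurably *below* 70.7% for steep psychometric functions (≈ 67–69% at
log-logistic scales of 0.15–0.3) and approaches the nominal level as the
psychometric spread grows relative to the step. The package's default
observer slope of 0.5 (in log-difference units) is both a realistic shallow
discrimination slope and inside the regime where the nominal level holds;
the convergence test and the acceptance script evaluate the observer's
percent-correct at the mean of 500 simulated run thresholds and obtain 71%
there. Users simulating steeper observers should expect the documented
downward bias — it is a property of the procedure, not of this
implementation.

## 5. Conflict-task scoring

Trials are trimmed in a single pass: incorrect responses are removed first;
then, per condition, correct trials beyond 2.5 standard deviations from that
condition's mean (both computed on the correct trials, i.e. after error
removal — the sentence order of the standard description) are removed.
Trimming is deliberately *not* iterated; a second pass could remove more, and
single-pass behaviour is the tested contract. A condition left with fewer
than two trials is an error, not a silent NA.

Three effects are reported, in a sign convention forced by the reported
negative medians of this literature:

* interference = mean RT(congruent) − mean RT(incongruent), *negative* when
  incongruent trials are slower;
* congruency = mean RT(neutral) − mean RT(congruent);
* incongruity = mean RT(incongruent) − mean RT(neutral).

They satisfy interference + congruency + incongruity = 0 exactly. Only the
interference effect enters the regressions; accuracy is recorded in the
trimming fractions but not analysed.

## 6. Screening and backward elimination

Candidate predictors are the three interference effects, the two
discrimination thresholds, and the two melody percent-correct scores.
`screen_predictors()` reports all pairwise Pearson correlations (r, r², p);
if the two melody scores are significantly correlated (p ≤ 0.05) they are
pooled into a single combined score — total correct over total trials across
both tasks, which for equal trial counts is their mean.

`fit_standardized()` z-scores *both* the outcome and the predictors before an
ordinary least-squares fit, the standard definition of standardized beta
weights (whether the outcome is standardized too is rarely stated in applied
reports; it does not affect t or p values, only the beta scale).
`backward_eliminate()` then removes the *single* predictor with the largest
p-value while that p exceeds 0.10, refitting after each removal —
"step-by-step" taken literally, one at a time, never in batches. The final
model is a fixed point: re-running elimination removes nothing further.

**A selection property worth stating plainly.** Under this stopping rule a
predictor that is pure noise survives with probability approximately equal to
the removal threshold (its final-stage p-value is uniform). With three
independent noise predictors, the chance that *all three* are eliminated is
therefore about $0.9^3 \approx 0.73$, no matter how strong the true
predictors are or how large the sample is. Monte-Carlo tests in this package
confirm the ~90% per-predictor drop rate and the ~73–77% joint rate on
200-participant synthetic cohorts. Any expectation that backward elimination
at p > 0.10 "cleans out" all irrelevant predictors in ≥ 90% of datasets is
mathematically unachievable; perfect-selection claims about this procedure
should be read with that bound in mind.

## 7. The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

**Speaker model.** The compensation state $p_t$ (a 2-vector of Hz offsets on
baseline F1/F2) evolves as

$$p_{t+1} = p_t + \lambda e_t - \alpha p_t, \qquad
e_t = \begin{cases} -(s_t + p_t) & \lVert s_t + p_t\rVert > \delta \\ 0 &
\text{otherwise,}\end{cases}$$

where $s_t$ is the scheduled feedback shift, $\lambda$ the corrective gain,
$\alpha$ a feedforward anchor pulling production back toward the habitual
target, and $\delta$ a dead zone implementing the auditory target region:
deviations smaller than $\delta$ trigger no correction. This dynamic is the
*package's* model — the verbal accounts it operationalizes (target regions
shrinking with acuity, partial compensation) do not specify equations. Its
fixed point under constant shift is $p^\* = -\frac{\lambda}{\lambda+\alpha}s$,
so steady-state compensation is the fraction $\lambda/(\lambda+\alpha)$ of
the full inverse alteration; the long-run simulation matches this closed form
to within 1% (tested at 10,000 hold trials). Stability requires
$\lambda + \alpha < 1$; violating it is a constructor error. Emitted formants
add Gaussian trial noise (default sd 10 Hz) and each trial is missing with
the tracking-failure probability (default 1%, the observed failure rate's
order of magnitude). The dead zone maps acuity $a$ as
$\delta = 120\,(1-a)$ Hz: a hypothetical zero-acuity speaker tolerates
120 Hz of feedback error, a maximally acute one none.

**Observer.** A two-interval forced-choice log-logistic observer:
$p(d) = \gamma + (1-\gamma-\ell)\,\mathrm{logistic}((\ln d - \ln\theta)/\sigma)$
with guess rate $\gamma = 0.5$, lapse $\ell$, threshold $\theta$ and slope
$\sigma$ (default 0.5; see §4 for why).

**Reaction times.** Gaussian RTs with condition means (neutral −
congruency gain, neutral, neutral + incongruity cost), sd 100 ms, 16 trials
per condition, 2% errors — the 48-trial task structure. Real RT distributions
are right-skewed; a Gaussian is sufficient here because only condition-mean
differences after symmetric trimming are consumed downstream.

**Melodies.** Integer-semitone random walks on a sampled major scale (5–13
notes, adjacent notes distinct and ≤ 5 semitones apart). "Different" pairs
move exactly one note: in the simple task by up to ±5 semitones staying in
key; in the transposed task (second melody 4 semitones up) by 1 semitone to a
pitch *outside* the transposed key. All changes preserve the melodic contour
(signs of successive intervals). Construction is rejection-sampled with a
bounded retry budget; every generated pair is property-tested against these
invariants. No audio is rendered.

**Cohort.** One latent acuity per participant (uniform on 0.05–0.95) drives
the speaker gain ($\lambda = 0.02 + 0.12a$, so steady-state compensation
spans ≈ 9–40% of the alteration, matching the empirically reported 1–41%
range), the dead zone, the observer thresholds (log-linearly decreasing in
acuity, calibrated so pitch thresholds span ≈ 0.3–3% and loudness ≈
0.4–2 dB), and melody accuracy (≈ 65–90%). The three executive effects are
drawn independently of acuity — the generator's null hypothesis — with
congruency gains ~N(15, 8) ms and incongruity costs ~N(30, 15) ms truncated
at zero. Every latent parameter lands in the ground-truth table. All
randomness flows from one master seed through per-participant substreams, so
bundles are bit-identical under a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: structured (non-independent) formant-tracker
failures, within-session drift and fatigue, skewed RT distributions,
inter-task correlations beyond the single acuity factor, attentional lapses
beyond a constant lapse rate, and any somatosensory contribution to
adaptation. Parameter-recovery results certify the pipeline's correctness
under its own generative assumptions, not the assumptions' fidelity.

## 8. The offline formant shifter

The analysis–modify–resynthesis chain mirrors the real-time device's frame
geometry offline: 400-sample analysis buffers at 11.025 kHz advanced in
32-sample hops, LPC order 12 (≈ rate/1000 + 2). Per frame: autocorrelation
LPC; the two lowest-frequency complex pole pairs with bandwidth < 400 Hz are
taken as F1/F2 (the selection rule is this package's; device descriptions do
not state one); their angles are rotated by $2\pi\,\Delta f/f_s$ with radii —
hence bandwidths — preserved; the frame's prediction residual is re-filtered
through the rebuilt all-pole polynomial, carrying pitch and temporal envelope
implicitly. Frames are Hann-windowed, overlap-added and weight-normalized,
and the output level is matched to the input (F1 pole movement otherwise
changes overall spectral amplitude audibly).

Numerical safeguards, each exercised by tests: a white-noise floor
(`r0 *= 1 + 1e-3`) conditions the Toeplitz solve so degenerate inputs such as
pure tones do not fabricate twin narrow poles; frames with fewer than two
formant candidates, near-silent frames, and frames whose resynthesis rings
are passed through unmodified (with a warning); edge samples whose
overlap-add weight is vanishing fall back to the input rather than dividing
by ~0. Round trips on a synthesized-vowel grid (F1 400–700, F2 1200–1800 Hz)
agree with requested shifts within ±25 Hz, and shifting by $v$ then $-v$
recovers the input within the same tolerance.

Out of scope: real-time streaming, the device's alternative narrow-band
spectral-envelope pathway (pole rotation is implemented; the two descriptions
coexist in the literature), and nasalized/side-branch vocal tracts for which
all-pole models are known to be unreliable — the very failure mode the
pipeline's missing-track handling exists for. `synthesize_vowel()` provides
impulse-train/resonator fixtures; WAV I/O is deliberately minimal (mono
16-bit PCM; anything else is refused, never silently converted).

## 9. Problem sizes and reproducibility

The test suite and acceptance checks use: 500 staircase runs for convergence
and start-independence; 10,000 hold trials for the speaker fixed point; a
3×3 vowel grid for shifter round trips; 1000 null fits for the adjusted-R²
calibration; and 100 seeds × 200 synthetic participants for full-pipeline
parameter recovery — sizes chosen so each check resolves its claim with
comfortable Monte-Carlo margin while the whole suite runs in minutes on one
CPU. Every stochastic test fixes its seed; `scripts/acceptance.R` derives all
randomness from its `--seed` argument.

## 10. Known limitations

* Vowel-interval extraction from audio is not implemented: formant *tracks*
  are the input contract; the shifter's `measure_formants()` averages over
  energy-gated frames and is intended for steady synthetic vowels.
* The staircase engine intentionally supports only n-down/1-up rules.
* Backward elimination inherits the selection property of §6; the package
  reports the full elimination trace so users can see, not guess, what was
  removed and why.
* The speaker model is a two-parameter linear update with a dead zone; it
  reproduces steady-state compensation fractions and approach dynamics but
  not trial-to-trial autocorrelation structure of real speakers.
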