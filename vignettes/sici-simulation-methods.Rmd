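---
title: "Simulating SICI protocols and their test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SICI protocols and their test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicitrack)
```

## The scientific problem

Short-interval intracortical inhibition (SICI) is a paired-pulse
transcranial magnetic stimulation (TMS) measure of GABAergic cortical
inhibition: a subthreshold conditioning stimulus (CS) delivered 1–7 ms
before a test stimulus suppresses the motor evoked potential (MEP).  Two
automated protocols quantify it:

* **T-SICI** (threshold tracking): the test stimulus is continuously
  adjusted to hold the MEP at a 0.2 mV target; inhibition appears as an
  elevation of the conditioned threshold, expressed in percent of the
  resting motor threshold (RMT), `T-SICI = (conditioned − RMT)/RMT × 100`.
  Positive values are inhibition.
* **A-SICI** (automated conventional): CS and test intensities are fixed;
  inhibition appears as a reduced conditioned/control MEP amplitude ratio,
  `A-SICI = geomean(conditioned)/geomean(control) × 100`.  Values below
  100 are inhibition.

Whether such measurements are stable enough for clinical decisions is a
test–retest reliability question.  This package simulates complete
multi-session reliability studies of both protocols on virtual subjects
and implements the full statistical battery used to analyse them, so that
the *properties* of the protocols and statistics (bias, convergence,
oracle correctness, reliability behaviour under known noise) can be
exercised where ground truth is known.  Raw human data from such studies
are not public; the simulator's role is to emulate their statistical
structure, not to reproduce individual published numbers.

## The virtual-subject model

Each subject is an `excitability_model()`:

* **Recruitment curve.** Over the 0.02–2 mV amplitude window the log MEP
  is linear in stimulus intensity:
  `log10(MEP) = log10(0.2) + b·(s − θ)`, where `θ` (`theta_true`, %MSO) is
  the intensity producing exactly 0.2 mV and `b` (`slope_b`,
  log10(mV)/%MSO) is the recruitment slope.  Outside the window the curve
  saturates smoothly to a noise floor (0.005 mV) and a ceiling (5 mV).
  The saturation tails are C1 exponential-approach curves attached at the
  window edges; a sigmoid over the whole range was rejected because it
  would bend the central segment, and exact linearity inside the window is
  what makes the threshold regression and the closed-form
  conditioned/control ratio hold without approximation error.
* **Trial-to-trial noise** is multiplicative: a normal deviate with SD
  `sigma_log` (log10 units) added in log space, reflecting the log-normal
  MEP amplitude distributions seen empirically.  The geometric mean at
  threshold is therefore exactly 0.2 mV.
* **Conditioning** at interstimulus interval (ISI) `i` shifts the curve
  rightward along the intensity axis by `Δ(i)`, stored as percent of `θ`
  in `inhibition_profile`.  This single mechanism generates both readouts:
  the conditioned threshold rises by `Δ` (T-SICI), and at a fixed test
  intensity the log amplitude ratio is `−b·Δ_abs` (A-SICI), which is why
  group-mean T-SICI and log10 A-SICI are linearly related across ISIs.
* **Session drift**: one additive normal shift of `θ` per examination
  (`session_drift_sd`, %MSO) emulating coil repositioning and diurnal
  excitability change.
* **Contamination**: each sweep carries a spontaneous prestimulus EMG peak
  with probability `contamination_rate`; peak amplitudes are exponential
  with mean `contamination_amp_mv`.  Sweeps whose peak exceeds the
  0.015 mV gate are discarded and redelivered.

### Cohort defaults and why

`cohort_params()` defaults describe a healthy adult cohort:

| parameter | default | rationale |
|---|---|---|
| `rmt_mean`, `rmt_sd` | 55.2, 8.4 %MSO | group RMT distribution of the emulated cohort; truncated to 20–95 %MSO so a test stimulus at 120% RMT stays deliverable |
| `slope_mean` | 0.065 log10(mV)/%MSO | places TS_1mV (the 1 mV intensity) near 120% of RMT, the empirically reported ratio |
| `sigma_log_mean` | 0.2 | typical single-trial MEP scatter of 1.5–2-fold |
| `inhibition_profile_mean` | 10.3/8/7/7.5/5.5/4/2/0/−4 at 1/1.5/2/2.5/3/3.5/4/5/7 ms | anchored at reported group T-SICI means for 1, 2.5 and 3 ms; other ISIs are free defaults giving the canonical shape (two inhibition peaks at 1 and 2.5 ms, decay, mild facilitation at 7 ms) |
| `inhibition_profile_sd_between` | 6 %RMT | matches the between-subject SD of band-averaged SICI (~6–7 %RMT); applied as one offset shared across ISIs, so some subjects are facilitators throughout, as observed in real cohorts |
| `session_drift_sd` | 2 %MSO | no directly citable value exists for the within/between-session split; calibrated so RMT repeatability coefficients land in the reported 5–10 %MSO range |
| `contamination_rate` | 0.02 | occasional incomplete relaxation |

These defaults are the study conditions; they are set once here and are
not adjusted per analysis.

## Threshold tracking and estimation

`proportional_step()` implements proportional tracking: the intensity
changes by `−gain·log10(MEP/target)`, clipped at `max_step` (2 %MSO for
initial RMT/TS_1mV tracking, 1 %MSO for in-protocol channels).  The gain
is not specified by the protocol description beyond "maximum step"
semantics; the package uses `gain = max_step` per log10 unit, so the full
step is taken only for a ten-fold-or-worse miss and the approach is
smooth.  An estimate is *valid* if the MEP hits the target within the 20%
log-scale tolerance (`|log10(MEP/target)| ≤ log10(1.2)`) or if consecutive
MEPs bracket the target line; tracking stops at six valid estimates
(counted cumulatively, not consecutively) with a safety cap of 100 trials.

`regression_threshold()` fits `log10(MEP) = α + β·intensity` over all
non-gated trials with amplitudes inside the 0.02–2 mV window and returns
`(log10(target) − α)/β`.  The fit is iteratively reweighted (Tukey
biweight, tuning constant 4.685, 3 iterations, scale = MAD) so that points
near the line contribute more.  Numerical policy:

* fewer than two usable trials, or a single distinct intensity → invalid;
* fitted `β ≤ 0` → invalid (not a recruitment curve);
* an intersection outside the deliverable 0–100 %MSO range → invalid.  No
  stimulator could deliver such a threshold, and without this rule rare
  near-zero slopes extrapolate to absurd values that dominate the
  estimator's variance;
* zero-amplitude responses are recorded at the noise floor and excluded by
  the window rule.

For the continuously tracked in-protocol channels a second, deliberate
fallback exists: those channels hover in a band of well under 1 %MSO, so
the regression slope is frequently unidentifiable even though the tracking
itself is healthy.  When the regression is invalid there, the channel
threshold is taken as the mean of the second half of the delivered
intensities — the proportional controller's feedback centres the delivered
intensity on the intensity whose expected log MEP equals the target, so
the tracking equilibrium *is* a threshold estimator; the first half is
discarded to shed the approach path.  Only channels with fewer than two
usable trials report a missing value.

## The two examinations

Both protocols deliver ten pseudorandomised cycles, each an independent
permutation of twelve conditions (nine ISIs and three control slots),
giving 90 paired and 30 control stimuli.  Gated sweeps are redelivered at
the end of the current cycle so the per-condition counts stay fixed
(capped at 24 redeliveries per cycle).  The prestimulus gate discards
peaks *strictly exceeding* 0.015 mV — a peak exactly at the gate is kept —
and the online 15 µV gate is modelled as the same mechanism rather than a
separate waveform check, since only scalar amplitudes are synthesised.

**T-SICI** (`run_t_sici()`): nine conditioned channels start at 120% of
the tracked RMT and move in 1 %MSO steps toward the 0.2 mV target; the
step doubles after two consecutive misses on the same side and resets once
the MEP lands within tolerance.  RMT is tracked concurrently on the three
control channels (proportional rule, 1 %MSO maximum step).  After every
cycle the CS is recomputed as 70% of the mean control-channel estimate.
Final thresholds come from the weighted regression (with the fallback
above); the examination's RMT pools all 30 control trials.

**A-SICI** (`run_a_sici()`): CS fixed at 70% of RMT and test stimulus
fixed at TS_1mV for the whole examination; per-ISI values are
geometric-mean ratios against the pooled control sweeps.

Band summaries (1–3.5 ms, 1–7 ms) are arithmetic means of per-ISI values
for T-SICI, and geometric-mean ratios over all member-ISI sweeps for
A-SICI.  A band value is computed over the member ISIs with usable
estimates; an examination with any missing ISI keeps `valid = FALSE`.

## The study design and runner

`run_study()` executes the default design — two days, morning and
afternoon sessions, each protocol twice per session (8 intraobserver
examinations per protocol), plus one second-observer examination per
protocol appended to one session (day 1 afternoon by default; the real
assignments varied for practical reasons, and the assignment is
configurable).  Every examination re-estimates RMT (and TS_1mV before an
A-SICI examination) from scratch, matching the procedure of repeating
hotspot/threshold estimation before each examination; the examination
drift is drawn before threshold estimation so that tracked and true
thresholds move together.  The tracker's starting intensity is 7 %MSO
above the subject's current true threshold, standing in for the manual
hotspot search that precedes tracking.  Observer 2 carries an optional
additive intensity offset (default 0, as no systematic observer bias was
modelled or reported).  Everything is reproducible from a single seed.

## The statistical battery

All reliability statistics operate on a `measurement_matrix()` (subjects ×
repeats; log10 scale for A-SICI, with listwise deletion of incomplete
subjects):

* `within_subject_sd()` — square root of the within-subject mean square of
  the one-way subjects ANOVA.
* `coefficient_of_repeatability()` — `CR = 1.96·√2·σw`; the 95% CI uses
  the exact χ² distribution of `σw²` with `n(k−1)` df.  The CI method is
  not named in the emulated analysis, so the χ² interval is this package's
  choice.  On the log10 scale the fold-change `10^CR` is also reported.
* `icc_2_1()` — two-way random effects, absolute agreement, single rating,
  `ICC = (MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE))`, with the
  standard F-based CI and the qualitative bands poor < 0.50 ≤ moderate
  < 0.75 ≤ good ≤ 0.90 < excellent (0.90 itself is "good", following the
  printed interval notation).
* `rm_anova()` — one within factor; Mauchly's W via the Box χ²
  approximation with the textbook second-order term (base R's
  `mauchly.test` uses a slightly different coefficient in that term; the
  two agree to ~1e−3), Greenhouse–Geisser ε from the contrast-projected
  covariance, applied when Mauchly's p < 0.05.  With a rank-deficient
  within-subject covariance (fewer subjects than conditions) Mauchly's
  test is unavailable; ε is then held at its lower bound `1/(k−1)` with
  a warning.  `pairwise_bonferroni()` provides the post hoc follow-up.
* `bland_altman()` — bias and 1.96·SD limits, back-transformed to ratios
  on the log10 scale.
* `one_sample_condition_test()`, `method_regression()` — per-ISI tests
  against the null condition (0 %RMT / 100% control MEP on the log scale)
  and the T-on-log10(A) inter-method regression with Fisher-z CI for r.

`summarize_reliability()` assembles the session-level CRs, the intraday,
interday and interobserver ICCs (first examination of the matching session
as the observer-1 reference), paired interobserver t tests and the
omnibus rmANOVA into one tidy table; `summarize_group_curves()` produces
the per-ISI group means (arithmetic for T, geometric for A), significance
flags, and the per-ISI and pooled inter-method regressions.

## What the simulation does and does not show

The generator reproduces the statistical skeleton the analysis assumes:
log-linear recruitment with log-normal scatter, threshold shifts as the
single conditioning mechanism, between-subject spread, session-level
drift, and occasional contamination.  It deliberately omits: EMG
waveforms and latencies, coil-position error as a separate process
(absorbed into `sigma_log` and `session_drift_sd`), stimulator charging
behaviour, amplitude-dependent variance and any floor effect in A-SICI
beyond the recruitment floor, and ISI-by-subject interaction beyond a
shared offset.  Because conditioning is a pure threshold shift, the
simulated A-SICI depth is exactly the recruitment-model image of the
T-SICI shift; in real cohorts conventional SICI is deeper than that
mapping predicts, so passing tests demonstrate internal consistency and
correct analysis, not fidelity of every published magnitude.  Reported
group medians/means of real subjects are likewise not reproduction
targets: the cohort is synthetic.

Test problem sizes were chosen to keep the whole suite comfortably
interactive: Monte-Carlo sampler checks at n = 10,000 draws, tracker bias
at 200 replicate tracks, protocol recovery at 100 replicate examinations,
and replicate-study properties at 20 single-session 10-subject studies
(repeatability averaging) and 2 × 8 studies (reliability vs noise).  The
full 18-subject, 9-examinations-per-protocol study with its complete
analysis runs in well under a minute.

## Worked example

```{r example, eval = FALSE}
ds <- run_study(cohort_params(n_subjects = 18), study_design(),
                protocol_config(), seed = 1)
rel <- summarize_reliability(ds)
curves <- summarize_group_curves(ds)

subset(curves$curves, isi %in% c(1, 2.5, 3, 7))
curves$pooled_regression$r2
subset(rel, parameter == "RMT_0.2mV" & statistic == "icc")
```

## Known limitations

* The equilibrium fallback for unidentifiable channel regressions trades
  a small lag bias (the channel inherits part of the starting RMT error)
  for robustness; with ten trials per channel this is the dominant
  within-examination error term for T-SICI.
* ICC confidence intervals use the asymptotic F-based method; with very
  small cohorts (n ≤ 4) the intervals are wide and the underlying qbeta
  computations can be inaccurate in the extreme tails.
* The rmANOVA is the complete-case, univariate approach; no mixed-model
  generalisation is attempted, and subjects with any missing cell are
  dropped listwise.
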