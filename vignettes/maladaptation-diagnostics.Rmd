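---
title: "Diagnosing maladaptation to exercise training load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing maladaptation to exercise training load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maladapt)
```

## The diagnostic model

Athletes who overreach accumulate fatigue, and when the training load
becomes excessive the overreaching turns maladaptive: intrinsic
mitochondrial respiration and glucose tolerance fall while performance is
not yet visibly impaired. No single field measurement separates an acutely
fatigued athlete from one sliding into non-functional overreaching, so this
package implements a multidimensional rule built from five easily
accessible parameters collected around standardized HIIT sessions:

| parameter | adverse direction | units |
|---|---|---|
| POMS fatigue subscale | increase | score |
| session maximal heart rate (highest 30-s mean) | decrease | bpm |
| end-of-session blood glucose | decrease | mmol/L |
| end-of-session blood lactate | decrease | mmol/L |
| session mean RPE | increase | Borg 6--20 |

The model has three ingredients:

1. **Individual baselines.** For each subject and parameter, the baseline
   is the mean over the *normal-reference* phases of the training
   schedule — by default BL, LT, MT1 and RE, i.e. phases whose
   measurements are unaffected by maladaptive load. MT2, a surveillance
   phase inserted to track the transition, is scored but never enters
   baselines or cut-offs.
2. **Group-derived cut-offs.** For each parameter the signed cut-off is
   half of the difference between the group mean under maladaptive load
   and the group mean under normal load,
   $q_p = (\bar{x}^{MAL}_p - \bar{x}^{norm}_p)/2$.
3. **Directional scoring and the 3-of-5 rule.** A subject-phase cell
   scores 1 when the deviation from the individual baseline exceeds the
   cut-off *strictly* in the adverse direction,
   $d_p\,(x - b) > d_p\,q_p$ with $d_p \in \{+1, -1\}$; a subject-phase
   accumulating at least 3 of 5 positive scores is flagged as showing
   maladaptation. In the reference cohort this rule flags all 11 subjects
   in the maladaptive phase and none in any normal phase.

```{r}
scores <- build_reference_score_matrix()
cl <- classify(scores, threshold = 3)
tapply(cl$flagged, cl$phase_id, sum)
```

## Design choices in the open

Several details are undetermined by the published description; the package
fixes them as follows.

* **Tie rule.** "Deviated more than the cut-off" is read as a strict
  inequality: a deviation exactly equal to the cut-off scores 0. Because
  measured values arrive in decimal form, the comparison adds a relative
  guard of $10^{-9}\max(1, |q_p|)$ so that a deviation equal to the
  cut-off up to binary floating-point representation also scores 0.
* **Cut-off precision.** Cut-offs are computed and applied at full
  precision. The published cut-off column is inconsistently rounded
  (4.65 prints as 4.7, but 0.715 prints as 0.71 and 0.625 as 0.62), so
  the printed values are treated as display artifacts;
  `fixed_cutoffs("published")` nevertheless lets users apply them
  verbatim, and the pipeline records which mode produced a report.
* **Pooling.** Group means pool every subject-by-phase observation with
  equal weight. Subject-first averaging (each subject one vote regardless
  of missing phases) is available as `pooling = "subject"`; with complete
  panels the two coincide.
* **Missing data.** A missing observation scores 0 and is counted in
  `n_missing` — conservative, since a missing value can never produce a
  false flag. A missing baseline phase reduces the baseline to the mean
  of the remaining normal phases with a warning; a parameter with no
  usable normal value at all is an error naming subject and parameter.
* **Individual cut-offs.** Per-subject cut-offs (half the subject's own
  MAL deviation) are exposed as an exploratory `cutoff_mode =
  "individual"`; with only a handful of normal observations per subject
  they are unstable, and the group-derived mode is the default.
* **Correlation.** The association between accumulated scores and the
  change in intrinsic mitochondrial respiration from each subject's
  normal mean is a single pre-specified Pearson correlation (two-sided
  p from the t-transform with $n-2$ df); no multiplicity correction.

## Session metrics

The diagnostic inputs are themselves derived quantities, computed here on
signals resampled to a uniform 1 Hz grid by linear interpolation
(`resample_1hz()`; export dialects differ and windowed statistics need a
fixed grid):

* `rolling_window_peak()` — the highest windowed mean over all contiguous
  windows (30 s for heart rate, 120 s for the VO2 plateau, 40 s for
  VO2max tests), sliding at 1-s steps with earliest-window tie-breaking.
* `heart_rate_recovery()` — the drop from the highest 30-s heart-rate
  mean of a work bout to the heart rate at fixed timepoints after the
  bout ends, averaged over a session's intervals.
* `brouwer_substrates()` — fat and carbohydrate oxidation from VO2/VCO2
  with the classical stoichiometric coefficients
  (fat $= 1.695\,\dot{V}O_2 - 1.701\,\dot{V}CO_2$,
  cho $= 4.170\,\dot{V}CO_2 - 2.965\,\dot{V}O_2$ g/min). The source
  publication for these coefficients predates digital supplements and the
  exact constants used by any given lab vary in the third decimal, so all
  coefficients are arguments with the defaults above, and reports retain
  the raw (unclipped) rates next to the zero-clipped ones whenever RER
  leaves the physiological 0.7--1.0 band.
* `poms_derived()`, `efficiency_ratios()`, `gross_efficiency()`,
  `initial_pacing_target()` — mood indices (TMD, EI), guarded exploratory
  ratios (never a silent infinity), and the 117% lactate-threshold pacing
  target for the first interval.

## The synthetic cohort

No subject-level data are distributed with the study design this package
models, so the generator reconstructs testable cohorts from what *is*
published:

* **The reference score matrix.** The published tables give, per phase,
  the number of subjects scoring positive on each parameter (column sums)
  and the number of subjects with at least $k$ of 5 scores (the row-sum
  distribution). Which subject holds which score is unidentified, so
  `build_reference_score_matrix()` fixes a canonical deterministic
  assignment: within each phase, score totals are assigned to subjects in
  descending order, and parameters — processed by descending count — give
  their positive scores to the subjects with the largest remaining
  totals (index-order ties). This column-wise largest-first construction
  is the bipartite Havel–Hakimi scheme and provably succeeds whenever the
  margins are Gale–Ryser feasible; a subject-first greedy that places each
  subject's scores into the currently least-saturated parameters can paint
  itself into a corner on these very margins, which is why the column-wise
  order is used. `randomize = TRUE` permutes the subject assignment for
  sensitivity checks.
* **Measurement panels.** `generate_measurements()` realizes any feasible
  score matrix as continuous panels. Positive cells are placed
  1.2--2.0 cut-offs beyond the baseline in the adverse direction and zero
  cells at most 0.8 cut-offs in that direction — margins chosen to keep
  values physiologic while leaving a comfortable strict-inequality gap.
  Inside the normal-reference phases the deviations of each
  subject-parameter are additionally constrained to average exactly zero,
  because the re-computed baseline is the mean of those very values; zero
  cells there absorb the compensating balance. The round trip
  (re-scoring the generated panels reproduces the input matrix) is
  verified post hoc with a bounded retry budget.
* **Respiration.** Subject-level normal respiration is drawn at
  100 ± 15 (arbitrary consistent units) with within-subject SD 8, and the
  maladaptive phase is shifted by −40% — the headline group effect. At
  zero noise the effect is exact by construction; at the default noise a
  1000-subject cohort reproduces it to well within ±2 percentage points.
  No record is generated for MT2 (no biopsy there).
* **Effect-model cohorts.** `simulate_cohort()` draws cohorts from a
  population model instead of a fixed matrix: maladaptive-phase effects
  equal to the published group mean differences, measurement noise SD of
  half the cut-off magnitude, between-subject baseline SDs set to
  figure-error-bar scale (POMS 6, HR 8 bpm, glucose 0.8 mmol/L, lactate
  2.5 mmol/L, RPE 1.0 — approximate and user-overridable), and half the
  effect in MT2. Under these conditions the 3-of-5 classifier attains
  near-perfect sensitivity in the maladaptive phase with a false-flag
  rate near zero in normal phases, and the score–respiration correlation
  is negative in essentially every simulated cohort.
* **Sessions.** `generate_session()` emits a 1 Hz monitored HIIT session
  (10-min 100 W warm-up, 2-min rest, five 4-min intervals with 3-min
  passive rests) with first-order heart-rate and VO2 kinetics — enough
  structure to exercise every windowed metric, with no pretension of
  modelling pacing strategy or breath-by-breath noise.

What the generator deliberately does **not** emulate: longitudinal
autocorrelation of mood, device-specific gas-exchange noise,
phase-to-phase drift of the "normal" phases, or any physiology of training
adaptation. Passing tests on synthetic cohorts therefore demonstrate that
the arithmetic of the model is correct and that the published count tables
are internally consistent — not that the classifier would retain its
published sensitivity on new athletes.

## Problem sizes and numerical conventions

The test suite exercises the score/classify path against a brute-force
oracle on 500 random cohorts of up to 12 subjects, the generator round
trip over 100 seeds, 500 simulated cohorts for the correlation-sign and
sensitivity/false-positive properties, and 1000 random series for the
rolling-window scan — sizes at which the brute-force references remain
exact and fast. Respiration calibration uses 1000 subjects. Degenerate
inputs fail loudly: series shorter than a window, zero-variance
correlation inputs, infeasible score margins (reported with the phase and
the violated Gale–Ryser bound), and thresholds outside 1..5 are all
errors, not silent results.

## Reproducing a full run

```{r}
panels <- generate_measurements(build_reference_score_matrix(), seed = 1)
respiration <- generate_respiration(seed = 1)
report <- run_pipeline(panels, respiration = respiration,
                       cutoff_mode = "fixed")
report
```

The same pipeline is available from a shell via the CLI script installed
under `system.file("cli", "maladapt.R", package = "maladapt")`, with
subcommands `derive-cutoffs`, `score`, `classify`, `metrics`, `simulate`
and `report`.

## Known limitations

* The published group means for the POMS fatigue subscale lie above the
  raw 0--28 range of the questionnaire, reflecting software-specific
  scaled scoring; the package treats POMS units as opaque score units.
* Whether the published group means were pooled observation-wise or
  subject-wise is not stated; both modes are provided and agree on
  complete panels.
* The subject-level joint structure of the reference matrix beyond the
  published margins is a modelling convention, not data.
* Cohort-level quantities that require the original subject-level data
  (e.g. the published score-respiration correlation coefficient) are
  reproduced only qualitatively (sign and approximate strength) on
  synthetic cohorts.
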