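---
title: "watchpd: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{watchpd: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `watchpd`, the parameters it exposes,
how the synthetic generator earns its realism, and the reasoning behind every
numerical choice. Code chunks are shown but not evaluated here; the README and
`scripts/acceptance.R` run the same calls end to end.

## 1. The assessment protocol and data model

A subject performs an 11-step protocol while wearing a smartwatch on each
wrist. Three steps last 20 seconds (two relaxed phases and one tremor
entrainment phase) and eight last 10 seconds; each step is labelled with a
task category — *Resting*, *Postural* or *Kinetic* — that determines which
tremor types it can elicit. Each watch records 3-axis acceleration and 3-axis
rotation at 100 Hz, so a full session holds
11 steps × 2 wrists × 2 sensors = 44 recordings, plus a 30-item binary
non-motor-symptom questionnaire spanning 9 domains (gastrointestinal, urinary,
apathy/attention/memory, hallucinations/delusions, depression/anxiety, sexual
function, cardiovascular, sleep/fatigue, miscellaneous).

`default_protocol()` returns the protocol as a plain data frame; every stage
of the pipeline accepts a custom protocol, which the test suite exploits with
a compact 3-step version.

Sessions are stored one JSON file per recording plus a `metadata.json`
(subject id, condition, gender, age, questionnaire). `write_session()` /
`read_session()` round-trip losslessly; reads validate axis counts, condition
and gender vocabularies, sampling rate and questionnaire length, and name the
offending file in every error.

## 2. The synthetic cohort generator

`generate_cohort()` draws per-subject *profiles* and then renders waveforms.
Realism comes from reproducing the mechanisms that make the real
classification problem hard, not from visual mimicry:

* **Condition phenotypes.** PD profiles draw a tremor frequency in 4–6 Hz,
  expressed only in *Resting*-category steps, with strong side dominance
  (laterality 0.7–0.95 — the non-dominant wrist receives the complementary
  share) and amplitude 0.02–0.10 g, deliberately reaching down to near the
  noise floor so classifiers cannot be perfect. DD profiles draw 5–8 Hz
  expressed in *Postural*/*Kinetic* steps with weaker laterality; HC profiles
  have no tremor. The frequency bands overlap at no point, but the amplitude
  and context structure — not a single threshold — is what separates classes.
* **Gravity and drift.** Acceleration channels carry a unit-norm gravity
  vector with a random orientation plus piecewise-linear drift, so that
  degravitation is genuinely necessary before spectral features make sense.
* **Onset artifact.** The first half-second of every recording contains a
  25 Hz, 0.05 g vibration burst emulating the start cue — the reason the
  pipeline trims 0.5 s.
* **Tremor envelope.** Tremor amplitude is modulated by a slowly varying
  log-normal envelope, so tremor energy fluctuates within a step as it does
  physiologically.
* **Rotation coupling.** Rotation channels receive the tremor with a gain of
  2, reflecting that wrist tremor is primarily rotational.
* **Demographics.** Gender marginals are condition-specific (PD male-skewed,
  HC female-skewed), which is exactly the confounding that motivates
  gender-by-class weighting and gender-matched evaluation downstream.
* **Questionnaire.** Items are independent Bernoulli draws with
  condition-specific probabilities, elevated for patients and most strongly
  for PD in the sleep/fatigue domain.

Every draw flows through one seed; `generate_cohort()` with equal
configuration is bit-reproducible, and per-stage seeds are derived by hashing
stage names so stages can be reproduced in isolation.

```{r}
library(watchpd)
cohort <- generate_cohort(generator_config(n_pd = 15, n_hc = 15, seed = 42))
```

## 3. Preprocessing

`preprocess_session()` applies, in order:

1. **Trim 0.5 s** from every recording head (onset artifact).
2. **Split** 20-second steps into two 10-second segments, so all segments are
   comparable task units; this is how 11 steps become 14 segments (and why a
   full subject has 14 × 12 = 168 channels).
3. **Truncate** all segments to the shortest common length (950 samples after
   trimming), guaranteeing a rectangular channel tensor.
4. **Degravitate** acceleration channels by subtracting an l1-trend-filter
   estimate of the gravity baseline (`trend_lambda = 1e4`). l1 trend filtering
   fits a piecewise-linear trend, which matches the generator's (and
   physical) gravity-plus-slow-drift model while leaving 1–19 Hz oscillation
   untouched; a high-pass filter would be simpler but distorts the tremor
   band's phase and leaks drift.
5. **Remove** three targeted-movement steps by default (`lift_hold`,
   `point_finger`, `touch_index`), leaving 11 segments / 132 channels; the
   removal set is a parameter.

### The l1 trend filter solver

No convex-optimization backend is available, so the solver is implemented in
Rcpp: the primal–dual interior-point method of Kim, Koh and Boyd on the dual
box-constrained QP, with the pentadiagonal Newton systems solved by a banded
LDLᵀ factorization — O(n) per iteration. Two numerical details matter:

* When λ ≥ λ_max = ‖(DDᵀ)⁻¹Dx‖∞ (the *slack regime*, where no box constraint
  is active), the exact solution is the least-squares line. The interior-point
  iteration stalls around 10⁻⁷ absolute suboptimality there, so the solver
  detects the regime — with one step of iterative refinement on the
  (DDᵀ)-solve, whose conditioning grows like n⁴ — and returns the closed-form
  line directly. λ = 10⁴ on 950-sample segments is usually in this regime.
* The duality gap provides a certified stopping criterion
  (relative tolerance 10⁻¹⁰); the test suite verifies objective optimality
  against independent candidate solutions across the λ range.

`degravitate()` returns `series - l1_trend_filter(series)`, so
trend + residual reconstructs the input to machine precision by construction.

## 4. Features

**Option A (manual, 31 per channel).** A Welch power spectral density with
1-second periodic-Hann windows at 50 % overlap; the one-sided density is
binned at the 19 integer frequencies 1–19 Hz and natural-log-transformed with
a 10⁻¹² floor (tremor is multiplicative, so log power linearizes amplitude
effects, and the floor keeps silent channels finite). Twelve more features
come from splitting the channel into 4 equal quarters and taking population
standard deviation, max |x| and energy Σx² of each — capturing within-segment
envelope dynamics the PSD discards. A full subject yields
31 × 168 = 5208 features.

**Option B (BOSS).** Each channel is converted into Symbolic Fourier
Approximation words: stride-1 sliding windows, optional per-window
z-normalization (which drops the DC coefficient), the first 4 real/imaginary
Fourier coefficients quantized into a 4-letter alphabet by equi-depth bins
fitted *on the training fold only*, and run-length numerosity reduction before
histogramming. Three window scales (20, 40, 80 samples) give a 3 × 256-word
histogram per channel. The implementation is validated against a brute-force
explicit-DFT oracle in the test suite.

## 5. Modeling

`evaluate_nested()` runs subject-level stratified nested cross-validation:

* **Folds** are assigned to whole subjects (never segments — the leakage
  canary in the acceptance suite corrupts test-fold features and asserts the
  inner selection is unchanged), stratified by class via round-robin after a
  seeded per-class shuffle.
* **Inner grid search** scores each candidate setup (input source × feature
  option × classifier) by mean inner-fold balanced accuracy and picks the
  first maximum (stable tie-break). A single-point grid short-circuits.
* **Weights.** Each (gender, class) group g receives weight
  w_g = N / (G · n_g), so every group carries equal total mass. `e1071::svm`
  only accepts per-class weights, so for the SVM the per-sample weights are
  aggregated to per-class means; xgboost, nnet and the stacking GLM receive
  the full per-sample weights.
* **Metrics.** Balanced accuracy (mean per-class recall, positive class PD),
  F1, precision, recall. Each test fold is also scored on a **gender-matched
  subset** (per-gender minimum cell size under-sampling, seeded) to expose
  gender shortcuts.
* **Classifiers.** RBF SVM (`e1071`), gradient-boosted trees (`xgboost`,
  single-threaded for determinism — standing in for any GBT implementation),
  and a feed-forward neural network (`nnet`). `nnet` supports one hidden
  layer, so the network has one hidden layer with width as a tunable
  parameter — a documented deviation from a two-layer default, which no
  installed package provides.

## 6. Stacking

`fit_stack()` trains the sensor model and the questionnaire model, collects
*out-of-fold* positive-class probabilities from an inner CV split of the
training fold as a 2-column meta-feature matrix, and fits an unpenalized
binomial GLM on it; the sub-models are then refit on the full training fold
for prediction. Out-of-fold meta-features are the standard guard against the
meta-learner rewarding sub-model overfit. `evaluate_stack()` reports sensor,
questionnaire and stacked rows per outer fold.

Stacking helps exactly when the modalities err on different subjects; the
acceptance suite constructs such a cohort (half the PD separable only by
tremor, half only by questionnaire) and verifies the stacked model beats both
single modalities. On small cohorts the meta-GLM can invert an anti-calibrated
sub-model — one reason the package defaults to 5 inner folds and the tests use
gradient-boosted trees for high-dimensional sensor features.

## 7. Grouped permutation importance

`stack_importance()` permutes feature *groups* — the three task categories for
sensor features, the nine symptom domains for questionnaire items — with a
shared permutation per group and repeat, and reports the mean balanced-accuracy
drop over repeats and outer folds. Grouped permutation respects the
correlation structure within a group (permuting single columns of a 31-feature
channel block understates importance) and yields exactly zero for groups the
model never consults, a property the test suite checks against a transparent
linear model.

## 8. Reproducibility machinery

* `with_seed()` evaluates an expression under a seed and restores the caller's
  RNG state.
* `derive_seed(seed, stage, index)` hashes stage names into independent
  31-bit seeds, so stages are reproducible in isolation and adding a stage
  never shifts another stage's stream.
* `run_pipeline()` writes every artifact plus a manifest with MD5 checksums
  and the derived stage seeds; identical configurations produce byte-identical
  artifacts.

## 9. Cohort sizes used in validation

The validation suite chooses cohort sizes by purpose, not convenience:
recovery runs use 100 + 100 subjects so fold-level balanced accuracy is a
stable estimate; the null calibration repeats 15 + 15 subjects over 20 seeds
(what matters there is the number of independent seeds, since the test
compares the grand mean against chance within standard error); structural
counts at the study scale (276 PD + 79 HC + 114 DD = 469) are recomputed from
profiles only, since waveforms add nothing to a count.

## 10. Limitations

* The generator is mechanistic, not learned: it reproduces tremor band,
  context, laterality, gravity, drift, onset artifact and demographic
  confounding, but not dyskinesia, bradykinesia-induced movement poverty,
  sensor dropout or real-world label noise. Pipeline performance on it bounds
  plumbing correctness, not clinical performance.
* Questionnaire items are conditionally independent given the class; real
  non-motor symptoms co-occur within domains.
* The neural network has a single hidden layer (see §5).
* Gender matching uses seeded under-sampling; on very small or very skewed
  folds the matched subset can be empty, in which case matched metrics are
  reported as `NA` rather than silently imputed.
* `xgboost` replaces the original CatBoost-style implementation; both are
  gradient-boosted tree ensembles but their regularization details differ.
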