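# watchpd

Smartwatch-based classification of Parkinson's disease (PD) against healthy
controls (HC) and differential diagnoses (DD), as an end-to-end, fully
reproducible R pipeline.

## Background

Movement disorders such as Parkinson's disease express themselves in wearable
inertial signals: PD typically shows a 4–6 Hz *rest* tremor that is strongly
side-dominant, while common differential diagnoses (e.g. essential tremor)
show a 5–8 Hz tremor under *postural* or *kinetic* load. A structured
assessment protocol — interleaving rest, posture-holding and targeted-movement
tasks while the patient wears a smartwatch on each wrist — makes these
contexts separable, and a short binary non-motor-symptom questionnaire adds a
complementary, movement-independent view.

`watchpd` implements that study design end to end:

1. **Synthetic cohort generator** — an 11-step assessment protocol (three
   20-second and eight 10-second steps), dual-wrist 3-axis acceleration and
   rotation at 100 Hz, condition-specific tremor phenotypes (frequency band,
   amplitude, laterality, task context), gravity with slow drift, a
   vibration-cue onset artifact, and a 30-item Bernoulli questionnaire over 9
   non-motor-symptom domains.
2. **Session I/O** — a documented one-JSON-file-per-recording session layout
   with lossless round trips and validating reads.
3. **Preprocessing** — onset trimming (0.5 s), splitting 20-second steps into
   two 10-second segments, truncation to a common segment length, and
   degravitation of the acceleration channels by subtracting an
   l1-trend-filter estimate of the gravity baseline (exact primal–dual
   interior-point solver, written in Rcpp).
4. **Features** — option A: Welch power spectral density (1–19 Hz, log scale)
   plus per-quarter segment statistics, 31 features per channel; option B:
   multi-scale Bag-of-SFA-Symbols (BOSS) word histograms.
5. **Modeling** — subject-level stratified *nested* cross-validation, inner
   grid search over input source × feature option × classifier (RBF SVM,
   gradient-boosted trees, feed-forward neural network), gender-by-class
   sample weighting, balanced-accuracy scoring, and gender-matched test
   subsets.
6. **Stacking** — out-of-fold probability stacking of the sensor model and
   the questionnaire model through a logistic meta-classifier.
7. **Importance** — grouped permutation importance over task categories
   (Resting / Postural / Kinetic) and questionnaire symptom domains.

Everything is seeded and deterministic: the same configuration reproduces
byte-identical artifacts.

## Worked example

Generate a cohort of 15 PD patients and 15 controls, preprocess and featurize
it, and evaluate a PD-vs-HC classifier with nested cross-validation:

```r
library(watchpd)

cohort <- generate_cohort(generator_config(n_pd = 15, n_hc = 15, seed = 42))
cohort[[1]]
#> <assessment_session> PD_001  condition=PD gender=female age=66
#>   44 recordings, 30 questionnaire answers

data <- build_cohort_data(cohort)
data
#> <cohort_data> 30 subjects (HC=15, PD=15)
#>   132 channels/subject, 4092 manual features, 30 questionnaire items

report <- evaluate_nested(
  data, c("PD", "HC"),
  list(grid_point("acceleration", "A", "svm"),
       grid_point("acceleration", "A", "gbt")),
  outer_k = 3, inner_k = 3, seed = 1)
report
#> <evaluation_report> PD vs HC, 3 outer folds, seed 1
#>  fold              setup balanced_accuracy      f1 precision  recall
#>     1 acceleration/A/gbt            90.00%  88.89%   100.00%  80.00%
#>     2 acceleration/A/gbt           100.00% 100.00%   100.00% 100.00%
#>     3 acceleration/A/gbt           100.00% 100.00%   100.00% 100.00%
#> mean balanced accuracy: overall 96.67% (5.77%)
```

Stack the sensor model with the questionnaire model and ask which feature
groups carry the signal:

```r
stacked <- evaluate_stack(data, c("PD", "HC"),
  sensor_grid = list(grid_point("acceleration", "A", "gbt")),
  outer_k = 3, inner_k = 3, seed = 2)
summary(stacked)
#>           group n_folds mean_balanced_accuracy sd_balanced_accuracy ...
#> 1        sensor       3              0.9333333           0.11547005
#> 2 questionnaire       3              0.8666667           0.05773503
#> 3       stacked       3              0.9666667           0.05773503

imp <- stack_importance(data, c("PD", "HC"),
  sensor_setup = grid_point("acceleration", "A", "gbt"),
  outer_k = 3, inner_k = 3, seed = 3, n_repeats = 20)
imp
#> <group_importance> baseline balanced accuracy 90.00%, 20 repeats
#>                     group mean_drop   sd_drop rank
#>             Resting tasks 0.2783333 0.1880381    1
#>             sleep/fatigue 0.1216667 0.1077420    2
#>            Postural tasks 0.0000000 0.0000000    3
#>             Kinetic tasks 0.0000000 0.0000000    4
#>  ...
```

The ranking recovers the generator's design: PD tremor is injected only in
resting-task context, and the PD questionnaire profile is elevated most in the
sleep/fatigue domain.

Sessions round-trip losslessly through the documented JSON layout:

```r
dir <- tempfile()
write_session(cohort[[1]], dir)
length(list.files(dir))   # 44 recordings + metadata.json
#> [1] 45
identical_session <- read_session(dir)
```

A single call runs the whole pipeline and writes all artifacts (feature
matrix, fold reports, importance table, manifest with checksums):

```r
run_pipeline(run_config(n_pd = 20, n_hc = 20, seed = 1, out_dir = "run1"))
```

## Command line interface

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "watchpd", package = "watchpd"))')
Rscript "$CLI" simulate --n-pd 5 --n-hc 5 --seed 7 --out cohort/
Rscript "$CLI" validate --dir cohort/PD_001
Rscript "$CLI" evaluate --dir cohort --task pd-vs-hc --out report.json
Rscript "$CLI" run-all --config config.json --out run1/
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "watchpd",
                   load_package = "installed")
```

The suite covers every module against hand-computed and brute-force oracles
(periodogram vs Welch peak bins, explicit-DFT SFA words, closed-form segment
statistics, l1-trend-filter objective optimality) plus end-to-end acceptance
properties (class recovery, chance-level null calibration, leakage canary,
stacking dominance on complementary modalities, importance ranking).

See `vignettes/watchpd-methods.Rmd` for the full methods description and the
reasoning behind every numerical choice.
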