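Package: watchpd
Title: Smartwatch-Based Classification of Parkinson's Disease and Differential Diagnoses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible analysis pipeline for dual-wrist
    smartwatch assessments of movement disorders. Provides a synthetic cohort
    generator emulating an 11-step clinical assessment protocol (3-axis
    acceleration and rotation at 100 Hz plus a 30-item binary non-motor-symptom
    questionnaire), JSON session input/output, preprocessing (onset trimming,
    20-second splitting, l1-trend-filter degravitation), two feature
    extraction options (Welch power-spectral-density and segment statistics;
    multi-scale Bag-of-SFA-Symbols histograms), subject-level nested
    cross-validation with gender-by-class sample weighting and gender-matched
    test subsets, multimodal classifier stacking with a logistic
    meta-classifier, and grouped permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp,
    e1071,
    xgboost,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
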