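Package: gazedx
Title: Eye-Tracking Biomarkers and Decision-Tree Integration for Early
    Autism Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for evaluating eye-tracking biomarkers of
    autism in young children evaluated in primary care. Implements low-level
    gaze signal processing (dispersion-based fixation detection, saccade
    extraction, calibration-accuracy and precision quality-control indices),
    computation of candidate biomarkers from five eye-tracking paradigms
    (nonsocial preference, gap-overlap attentional disengagement, pupillary
    light reflex latency and amplitude, tonic pupil size, fixation duration),
    univariate and covariate-adjusted logistic screening with ROC/AUC,
    direction-aware cut points at fixed 95% specificity, an any-positive
    composite biomarker index with full diagnostic-accuracy statistics
    (sensitivity, specificity, PPV, NPV with Wilson intervals, Cohen's kappa),
    and a classification-and-regression-tree integration of the composite
    biomarker with primary-care practitioner diagnosis and diagnostic
    certainty yielding three-way diagnose / rule-out / refer decisions with
    stratified cross-validation. A seeded synthetic-cohort generator produces
    biomarker tables, practitioner labels and raw gaze/pupil streams with
    known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse
Config/testthat/edition: 3
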