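Package: dialacc
Title: Wrist-Accelerometer Physical Activity Analysis for Haemodialysis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing wrist-worn triaxial
    accelerometer data in haemodialysis cohorts: unit-sphere autocalibration
    and ENMO (Euclidean norm minus one) vector-magnitude summarisation of raw
    traces, non-wear detection with dialysis-aware excellent-wear criteria,
    stratified time-of-day imputation onto a one-minute grid, balanced
    random-forest classification of five functional behaviours (walking,
    light tasks, moderate-intensity activity, sedentary, sleep) with hidden
    Markov model time smoothing, KCCQ and EQ-5D-3L questionnaire scoring, and
    the cohort statistics used in dialysis accelerometry studies (day-type
    contrasts, covariate-adjusted marginal means, Spearman correlations,
    time-of-day profiles, matched-control comparison). A calibrated synthetic
    cohort generator supplies raw- and epoch-tier data with known truth so
    every stage is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    withr
Config/testthat/edition: 3
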