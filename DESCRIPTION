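Package: gazescratch
Title: Gaze-Contingent Scratch Paradigm Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing gaze-contingent "scratch"
    experiments with infants, in which gaze over a covered image uncovers the
    picture beneath. Provides an offline re-implementation of the trial
    mechanics (phase schedule, cover grid, gaze-driven uncovering, stop rule),
    dispersion-duration (I-DT) fixation detection, differential looking scores
    (DLS) against corner-quadrant areas of interest with preregistered
    exclusion rules, subject-level aggregation, and a Bayesian inference layer:
    default-prior (JZS) one-sample Bayes factors, a latent-normal rank-based
    Bayes factor, Kendall tau-b association Bayes factors, evidence
    classification, and sequential-design monitoring and calibration. A
    synthetic-cohort generator produces infant-like gaze recordings with known
    ground truth so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
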