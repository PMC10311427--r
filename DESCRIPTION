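Package: digirop
Title: Retinopathy of Prematurity Treatment-Risk Models and Screening
    Decision Support (DIGIROP 2.0)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the DIGIROP 2.0 family of risk models for
    retinopathy of prematurity (ROP) treatment: a prescreen time-to-treatment
    hazard model fitted by extended Poisson regression on split person-time
    with a restricted cubic spline baseline, weekly screen logistic models
    for postnatal weeks 6 to 14 that combine the prescreen log-odds with
    ROP detection status and timing, and calibration of gestational-age
    specific probability cutoffs that enforce 100% training sensitivity for
    a screening discharge decision-support tool.  Includes a synthetic
    registry-like cohort generator with known ground-truth hazard, the
    statistical primitives used in the accompanying prognostic analysis of
    parenteral nutrition duration (exact binomial and Miettinen-Nurminen
    score intervals, odds ratios, ROC/Youden cutoff search, the
    Hosmer-Lemeshow test, the sign test), a cross-validation and temporal
    validation harness, and a G-ROP rule-based comparator engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
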