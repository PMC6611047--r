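Package: sciatriage
Title: Development of a Subgrouping Algorithm for Sciatica Referral Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and evaluating a rule-based algorithm that
    subgroups primary-care patients with sciatica into three matched care
    pathways. Implements STarT Back tool scoring and prognostic risk
    classification, derivation of four clinical referral characteristics,
    block-wise logistic-regression selection of factors associated with
    specialist referral (with pairwise-correlation and variance-inflation
    collinearity screening), bootstrap optimism-corrected discrimination and
    calibration-slope internal validation, scenario-based evaluation of
    fast-track referral rules with Wilson confidence intervals, and a
    calibrated synthetic-cohort simulator for testing the whole pipeline
    against published aggregate results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
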