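Package: asiskit
Title: Annual Severity Increment Score Analysis for Niemann-Pick Type C Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal clinical severity in
    Niemann-Pick disease type C with the annual severity increment score
    (ASIS): composite severity scoring on the NIH clinical severity scale
    minus hearing, per-patient progression-rate estimation and Tukey-whisker
    stability classification, latent-class mixture regression of severity on
    age with nearest-line subgroup assignment, exhaustive Spearman subset
    scans of major subdomains against the composite score, questionnaire
    rank aggregation, simulated clinical-trial eligibility under age and
    ASIS bands, through-origin trajectory prognosis scored by per-patient
    maximum absolute deviation, random-intercept mixed-model estimation of
    on-treatment ASIS change, and a seeded synthetic cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
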