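Package: ctdnakit
Title: Longitudinal ctDNA Kinetics, Landmark Survival Models and Trial
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing longitudinal circulating tumor DNA (ctDNA)
    kinetics in randomized oncology trials: post-processing of per-variant
    read counts into censored, PBMC-corrected allele fractions and per-sample
    tumor burden (mean tumor molecules per mL plasma); derivation of per-visit
    ctDNA level and change metrics with landmark feature-matrix assembly,
    median imputation and interquartile-range scaling; landmark-rebaselined
    elastic-net Cox modelling with leave-one-out cross-validation, nested
    penalty selection, retention/next-door feature ranking and molecular
    response calling (mPD/mSD/mResp); Harrell concordance index with
    asymptotic standard errors and paired comparison; and simulation of early
    go/no-go operating characteristics with false-go calibration. Includes a
    synthetic randomized-cohort generator with the longitudinal, survival and
    radiographic structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
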