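Package: ildgapc
Title: Comorbidity-Extended ILD-GAP Prognostic Staging and Survival Model
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prognostic staging of interstitial lung disease (ILD)
    with the ILD-GAP index and its comorbidity-extended variant ILD-GAPC,
    which adds a categorised Charlson Comorbidity Index score (CCIS) term.
    Provides Charlson comorbidity scoring from 19 condition flags, point
    assignment and stage / risk-group classification, definitions of 3-year
    ILD-related event and all-cause mortality endpoints under right
    censoring, a calibrated proportional-hazards synthetic cohort simulator,
    and from-formula survival statistics (Kaplan-Meier with Greenwood
    variance, k-group log-rank, univariate Cox partial likelihood with Efron
    tie handling, Harrell's concordance index, inverse-probability-of-
    censoring-weighted time-dependent ROC AUC, and Cox AIC), together with an
    analysis pipeline that compares the two scoring models on a cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
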