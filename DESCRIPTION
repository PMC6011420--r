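Package: phthalmix
Title: Phthalate Mixtures and Time to Delivery: Risk Scores, Repeated
    Measures and Survival Models for Pregnancy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating mixtures of urinary phthalate metabolite
    concentrations to gestational age at delivery. Implements exposure
    processing for urinary biomarkers (limit-of-detection substitution,
    specific-gravity dilution correction, molar summation of DEHP
    metabolites, visit averaging, IQR standardization), summative
    risk scores (environmental risk score and weighted quantile sum with
    bootstrap-estimated non-negative weights), a two-stage random-intercept
    mixed-model treatment of repeated exposure measurements with BLUP
    extraction, and inverse-probability-weighted logistic, Cox
    proportional-hazards and lognormal accelerated-failure-time outcome
    models. A synthetic cohort generator reproduces the data structure such
    analyses assume (correlated lognormal exposures with configurable
    intraclass correlation, visit attrition, nested case-control sampling
    with design weights) for validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    lme4,
    sandwich,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
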