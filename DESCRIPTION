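Package: ehrtmle
Title: Targeted Learning of Blood Pressure-Cardiovascular Risk Ratios from
    Longitudinal Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal electronic-health-record cohorts of patients
    with diabetes in which a latent frailty confounds the relationship between
    systolic blood pressure (SBP) and cardiovascular outcomes, with known
    counterfactual risks as ground truth. Implements the full observational
    study design (entry at first qualifying blood-pressure measurement,
    12-month baseline exposure averaging, six SBP categories, composite
    cardiovascular outcome over months 12-120, sensitivity variants), a compact
    transformer over coded diagnosis/medication histories trained jointly for
    propensity and outcome with masked-sequence pretraining and 5-fold
    cross-fitting, cross-validated targeted maximum likelihood estimation
    (CV-TMLE) of marginal risk ratios with influence-curve confidence
    intervals, and conventional comparators (crude risk ratios, chained-equation
    multiple imputation with standardized logistic regression, Cox
    proportional-hazards checks), with forest-table reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
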