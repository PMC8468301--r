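Package: ifxmipd
Title: External Evaluation of Infliximab Population Pharmacokinetic
    Models for Model-Informed Precision Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to externally evaluate published infliximab population
    pharmacokinetic models in inflammatory bowel disease in a Bayesian
    forecasting setting. Provides NONMEM-convention event-table input with a
    documented exclusion cascade, declarative one- and two-compartment model
    configurations with covariate, inter-individual, inter-occasion and
    residual variability components, exact piecewise-analytic infusion
    kinetics, maximum a posteriori (MAP) empirical Bayes estimation from a
    single anchor concentration, forecast accuracy and bias metrics (median
    symmetric accuracy and symmetric signed percentage bias), dose-escalation
    classification against the 5 microgram/mL trough target, prediction- and
    variability-corrected visual predictive checks, and a synthetic cohort
    generator emulating a routine therapeutic drug monitoring data set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
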