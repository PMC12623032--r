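Package: ipirisk
Title: Diabetes Risk Prediction with Individualized Preventive Intervention Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop and validate proportional-hazards risk models
    with treatment-covariate interactions for diabetes prevention. Simulates
    randomized-trial and observational cohorts with configurable covariate
    distributions and hazard structure, imputes missing predictors by
    Gower-distance k-nearest-neighbour aggregation, fits Cox models with
    arm-specific effects by Newton-Raphson on the partial likelihood (Efron
    or Breslow ties) with a Breslow baseline cumulative hazard, computes
    counterfactual 3-year risks under lifestyle, metformin, and no
    intervention, assigns optimal prevention strategies and evaluates
    treatment policies by number needed to treat, and validates predictions
    with discrimination, decile calibration, net reclassification,
    decision-curve net benefit, fairness gaps, and Brier/IPA metrics under
    inverse-probability-of-censoring weighting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
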