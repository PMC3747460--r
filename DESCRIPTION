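Package: pshazard
Title: Propensity Score Methods for Marginal Hazard Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation framework for comparing propensity score
    methods (1:1 greedy caliper matching, stratification on quintiles, inverse
    probability of treatment weighting, and covariate adjustment) when
    estimating marginal hazard ratios from time-to-event data. Includes a
    Weibull data-generating process with prevalence-calibrated treatment
    selection, a potential-outcomes bisection algorithm linking conditional and
    marginal hazard ratios (ATE and ATT framings), nine Cox-model treatment
    effect estimators, and a performance-metric battery (bias, relative bias,
    MSE, SE/SD ratio, coverage, confidence interval length). The estimator
    functions also accept user-supplied survival data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
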