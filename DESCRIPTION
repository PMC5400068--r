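Package: lacecurve
Title: Nonlinear Exposure-Outcome Curves from Stratified Instrumental-Variable Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiparametric instrumental-variable estimation of nonlinear
    exposure-outcome relationships for Mendelian randomization. Stratifies a
    cohort on the IV-free exposure (control function), estimates a localized
    average causal effect (LACE) in each stratum, and summarises the strata
    either by fractional-polynomial metaregression on the derivative scale or
    by a continuous piecewise linear curve, with analytic or bootstrap
    confidence bands anchored at a reference exposure. Includes Cochran Q,
    quadratic trend and fractional-polynomial likelihood-ratio tests of
    nonlinearity, weighted allele-score construction, and a simulation module
    for assessing bias, coverage and test power under configurable
    data-generating models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
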