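Package: codtip
Title: Tipping-Point Diagnostics for Exploited Fish Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A three-stage evidence chain for detecting regime-shift and
    tipping-point dynamics in exploited fish populations from annual
    stock-assessment time series (spawning stock biomass, recruitment,
    fishing mortality, sea surface temperature).  Stage one detects
    multiple changepoints in the mean of single series with an exact
    penalized dynamic program (PELT).  Stage two locates multiple
    structural breaks in bivariate linear relationships by residual
    sum-of-squares dynamic programming with BIC model selection.  Stage
    three fits the stochastic cusp catastrophe model by maximum
    likelihood on its stationary density, classifies yearly system
    states as stable or bistable via Cardan's discriminant, and
    validates the fit against linear and logistic alternatives.  A
    synthetic-data module generates regime-structured series and
    cusp-process observations so the whole pipeline is testable without
    access to assessment databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
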