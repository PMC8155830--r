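Package: ewmrsr
Title: County-Level Opioid Abuse Severity Evaluation, Forecasting and
    Policy Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the severity of county-level opioid abuse
    from forensic drug-report surveillance tables. Computes four spread
    indicators (opioid share, count and share change rates, and a
    neighbor odds-ratio), combines them with entropy weights into
    rank-sum-ratio scores smoothed by a probit regression, classifies
    counties into ordinal severity levels, forecasts future severity with
    autoregressive models, relates the indicators to census demographic
    variables via LASSO regression with leave-one-out cross-validation,
    and simulates the effect of demographic-targeted policies on severity
    scores. Includes a synthetic-data generator emulating the surveillance,
    coordinate and census tables so the whole pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    geosphere,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
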