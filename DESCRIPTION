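Package: carbontarget
Title: Spatial Targeting of Voluntary Agricultural Carbon Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing where voluntary agricultural greenhouse-gas
    mitigation programs are likely to be cost-efficient. Implements a Gaussian
    threshold model of conservation-practice adoption with carbon-credit
    additionality accounting, a synthetic county-panel generator, construction
    of degree-bin temperature exposures and related climate, soil and program
    features, honest regression forests for forecasting county adoption rates
    with out-of-bag calibration testing, and a bivariate (adoption-rate
    interval by sequestration tercile) cost-efficiency classification of
    counties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    Rcpp,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
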