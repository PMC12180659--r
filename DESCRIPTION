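Package: gutload
Title: Stochastic Models of Gut Bacterial Load in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the variance of bacterial load across populations of
    mono-colonized Caenorhabditis elegans hosts. Provides a stochastic
    colonization/birth/death null model with exact Gillespie simulation and
    mean-field fitting, host-heterogeneity ensembles with a discretized
    three-level likelihood and grid search, a saturating log(CFU) to
    log(GFP) fluorescence calibration, two-component Gaussian mixture
    summaries of load distributions, an explicit two-state switching model
    with master-equation occupancy dynamics, and a multiwell-potential
    (Kramers) model with noise estimation, plus synthetic-data generators
    that emulate both destructive CFU sampling and longitudinal
    fluorescence measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    mclust,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
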