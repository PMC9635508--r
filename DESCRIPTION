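Package: grainfill
Title: Richards Growth-Curve Analysis of Rice Grain Filling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits the four-parameter Richards growth equation to grain
    dry-weight time series from japonica rice and derives the kinetic
    characteristics of the grain-filling process: initial relative growth
    rate, maximum and average filling rates, the time and weight at peak
    filling, active filling duration, and the start/middle/late sub-phase
    decomposition defined by the inflection points of the rate curve.
    Includes bounded multi-start nonlinear least-squares fitting with
    convergence diagnostics, Pearson and partial correlation tools for
    linking filling characteristics to yield components and grain-quality
    traits, a synthetic-data generator emulating a two-site two-year field
    study at high latitudes, and an end-to-end pipeline with CSV input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
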