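Package: imapr
Title: Integrative Modelling of Age-Performance Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Fits, simulates and compares lifespan trajectories of top
    performance across species. Implements an integrative model of age
    performance in which a saturating cell-population growth factor is
    multiplied by an exponentially accelerating loss of cellular
    functionality that vanishes at an explicit time of death, together
    with the classical Moore double-exponential curve and the Siler
    mortality hazard as reference models. Provides per-age top-performance
    envelope extraction from raw records, Levenberg-Marquardt nonlinear
    least-squares estimation with goodness-of-fit and AICc/dynamic-time-
    warping model comparison, Monte-Carlo credibility envelopes from the
    fitted parameter covariance, peak-age and time-constant derivation,
    and a synthetic-data generator emulating ranking-style performance
    cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
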