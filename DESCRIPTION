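Package: pelletdsm
Title: Density Surface Modelling of Deer Pellet-Group Distance-Sampling Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of dung pellet-group line-transect surveys for
    mapping relative ungulate abundance. Stage one fits and selects multiple-
    covariate distance-sampling detection functions (half-normal and hazard-rate
    keys, adjustment series, observer post-stratification, Cramer-von Mises
    goodness of fit). Stage two corrects segment counts with a Horvitz-Thompson
    estimator and models them with penalized additive regressions (tweedie or
    negative binomial) on buffered landscape covariates, predicts abundance on a
    regular grid with delta-method uncertainty, evaluates extrapolation with
    ExDet and percentage-of-data-nearby metrics, and validates district-level
    summaries against harvest densities. Includes a synthetic survey generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1),
    mgcv
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
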