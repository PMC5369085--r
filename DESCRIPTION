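Package: aerowarn
Title: Air Quality Early Warning: Hybrid Decomposition Forecasting and
    Cloud-Model Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An air-quality early-warning toolkit for hourly pollutant
    concentration series (PM2.5, PM10, O3, CO, NO2, SO2). Point
    forecasting couples complementary ensemble empirical mode
    decomposition (CEEMD) with a least-squares support vector machine
    whose kernel width and regularisation are tuned by a
    biogeography-based optimizer hybridised with differential evolution
    (BBODE). Nonsymmetric prediction intervals are built from the
    linear-smoother representation of the fitted model via bias
    correction and residual-variance smoothing, scored by coverage
    probability and average width. Forecast vectors are graded into six
    air-quality levels by a normal/half cloud model with entropy-AHP
    criterion weights and Monte-Carlo certainty aggregation. Parametric
    marginal distributions (Weibull, Gamma, Lognormal, Log-logistic,
    Inverse Gaussian) are fitted by maximising cumulative-distribution
    goodness of fit with the same optimizer, and forecasting models are
    compared with the Diebold-Mariano test.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    readr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
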