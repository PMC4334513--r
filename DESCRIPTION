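Package: tamsdfit
Title: Precision and Bias of Anomalous-Exponent Estimates from
    Time-Averaged MSD Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Benchmarks and guidelines for estimating the anomalous
    diffusion exponent from single-particle-tracking trajectories by
    power-law fitting of the time-averaged mean square displacement
    (TAMSD). Simulates fractional Brownian motion with unit-normalized
    increments and additive Gaussian localization noise, fits the TAMSD
    on log-log axes up to a maximal lag, and maps the estimator's
    precision (fraction of fits within +/-0.1 of the truth) and bias over
    trajectory length and maximal lag by Monte Carlo. Includes the
    localization-noise offset correction, a sub-sampling transform for
    large relative noise, optimal maximal-lag extraction, a quick lookup
    table of recommended maximal lags, and a recommender that encodes
    fitting guidelines for known, approximate and unknown noise levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
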