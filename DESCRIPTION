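Package: stringair
Title: Lockdown Policy Stringency, Air-Pollution Change, and Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to link the stringency of COVID-19 lockdown policies to
    modelled changes in urban air pollution and the resulting short-term
    mortality burden. Builds the 0-100 Stringency Index (and leave-one-out
    variants) from nine standardized policy indicators, fits a spatially
    structured Bayesian non-linear mixed-effect model of pollutant change
    on stringency (natural-spline exposure-response with city-level spline
    deviations carrying Matern Gaussian-process covariance under penalized
    complexity priors), decomposes the effect of individual policy measures,
    and converts pollutant changes into attributable deaths with parametric
    Monte-Carlo uncertainty. Ships a synthetic-data generator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
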