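Package: sagloc
Title: Sagittal-Plane Sound Localization Modelling with Spectral Weighting Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Template-matching model of human sound localization in sagittal
    planes based on positive spectral gradients of directional transfer
    functions (DTFs), extended with configurable spectral weighting schemes
    (flat, notch-region, discrimination-task, spatial-variance and low-pass
    weights). Includes a parametric synthetic-listener generator, maximum
    likelihood fitting of the model parameters (selectivity, sensitivity and
    sensorimotor scatter), BIC-based evidence tables, random-effects Bayesian
    group model selection (protected exceedance probabilities and Bayesian
    omnibus risk), Nagelkerke goodness of fit, and quadrant-error / polar-error
    localization metrics.
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
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
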