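Package: mortclubs
Title: Mortality Convergence Clubs from Abridged Life Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools to study convergence and divergence in human longevity from
    abridged life tables. Builds complete life tables from age-grouped death
    probabilities, computes nine longevity indicators (life expectancy at birth
    and at 65, modal age at death, Gini index and conditional standard
    deviation of lifespans at birth and at 65, and two survival percentiles),
    fits and forecasts a logit-link Lee-Carter mortality model per population,
    groups countries into convergence clubs with hierarchical K-means, and
    quantifies beta- and sigma-convergence across countries. Includes a
    synthetic abridged-life-table generator with planted mortality regimes so
    the whole pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
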