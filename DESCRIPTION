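Package: ibexdyn
Title: Stochastic Density- and Climate-Driven Population Dynamics for Alpine Ibex Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits, simulates and validates stochastic log-growth population
    models in which annual growth depends on population density (raw or
    log-transformed), winter precipitation, and their interaction. Provides
    ensemble forecasting with empirical prediction bands, out-of-sample
    validation against census counts, and model-based detection of the first
    year observations leave the band (an "alarm bell" for causes beyond
    density and climate). Includes a synthetic-data generator for census,
    winter-climate and warden-headcount series with optional removal
    interventions, founder-population scenarios and missing-year gaps, plus
    CSV readers/writers and a scripted command-line interface so every
    analysis is reproducible from a single seed.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
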