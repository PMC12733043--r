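Package: freshfit
Title: One-Step Baranyi-Ratkowsky Growth Modelling and Quality Metrics
    for Fresh Produce
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Shelf-life analysis tools for fresh produce storage trials.
    Implements the Baranyi primary growth model coupled with the
    sub-optimal Ratkowsky secondary model, fitted to plate counts from
    several storage temperatures in a single global (one-step) nonlinear
    least-squares step, with AIC-based selection between lag and no-lag
    variants and z-tests for comparing parameter estimates between
    packaging treatments. Also provides seeded generators that emulate a
    cherry tomato / kale storage design (including a 2 log CFU/g plate
    count detection limit), CIELab colour indices (chroma, hue angle,
    tomato colour index, yellowness index, total colour difference),
    spectrophotometric chlorophyll and carotenoid equations with
    fresh-weight conversion, and Spearman correlation plus linear
    regression tools for quality tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
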