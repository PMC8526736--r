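Package: rhythmfit
Title: Damped Cosinor Modelling and Randomization Inference for
    Gene-Expression Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits damped sinusoid (cosinor-with-decay) models to replicated
    gene-expression time courses sampled against zeitgeber time, summarises
    the fitted rhythm (MESOR, amplitude, period, peak and nadir timing), and
    tests condition effects on the MESOR with a condition-shuffled hybrid
    time-series randomization. Includes reference-gene normalization and
    per-gene Z-scaling for count panels, efficiency-corrected relative
    expression for qPCR, linear-fit analysis of oxygen consumption rate
    series with two-factor comparison and Sidak adjustment, and a
    seed-reproducible synthetic-data generator emulating the sampling
    designs the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
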