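Package: n15rates
Title: Rate Calculation and Calibration for 15N Tracer Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes nitrification and nitrogen uptake rates from 15N
    stable-isotope tracer incubations. Provides isotope mass-balance
    bookkeeping (delta/atom-fraction conversion, tracer spikes, carrier
    additions, blank corrections), rate equations with in-situ calibration
    for tracer-enrichment bias, per-sample detection limits,
    Michaelis-Menten kinetic fitting with substrate affinity, daily rate
    integration, water-column feature detection (mixed-layer depth,
    nitracline, euphotic depth, nitrite and chlorophyll maxima, and the
    uptake-to-nitrification transition depth), and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
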