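Package: qalyvsl
Title: Monetary Valuation of Quality-Adjusted Life Years from a Life-Cycle
    Value of Statistical Life Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes age- and scenario-specific values of a statistical life
    (VSL), life-extension values (LEV) and monetary values of a
    quality-adjusted life year (QALY) from age-indexed socioeconomic tables
    (survival, full income, full consumption, population). Lifetime
    quality-of-life trajectories are built from declarative scenario
    specifications under an equal-area constraint solved for a terminal age,
    and healthcare-policy cost reductions are evaluated against a fixed
    conventional QALY benchmark under arbitrary scenario-proportion mixes.
    Includes a seeded generator of Japan-like synthetic inputs so the whole
    pipeline runs without external data, tidy accessors for every result
    type, ggplot2 visualisations, and a configuration-driven command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
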