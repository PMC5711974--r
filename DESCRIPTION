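Package: fluxbudget
Title: Soil CO2 Efflux Modelling and Forest Carbon Budgeting After Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chamber-based soil CO2 efflux estimation, per-plot exponential
    (Q10) temperature-response modelling with annual upscaling from continuous
    soil-temperature records, partitioning of soil respiration into autotrophic
    and heterotrophic components via trenching and clipping experiments and a
    fine-root-carbon scaling rule, litter carbon-input estimation, and assembly
    of net ecosystem productivity budgets for forest chronosequence sections.
    Includes a seeded synthetic-data generator that emulates the design of a
    plot-based field campaign so every stage can be tested against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
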