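Package: fieldctmax
Title: Field Critical Thermal Maximum Analysis for Stream Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing field-based critical thermal maximum (CTmax)
    studies of stream fishes. Imputes gaps in hourly stream-temperature series
    from lagged air temperature using competing linear and logistic transfer
    models, computes acclimation-window and seasonal thermal metrics, selects
    the best acclimation window for predicting CTmax with random-intercept
    linear mixed models compared by AIC, fits an additive model with a
    penalized body-size smooth, and derives per-site thermal safety margins,
    sublethal-threshold exceedance summaries, and the acclimation response
    ratio. Includes a synthetic-data generator that emulates the statistical
    structure of a multi-site field study so the whole pipeline can be
    exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    mgcv,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
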