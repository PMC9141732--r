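Package: esvland
Title: Ecosystem-Service Valuation and Multi-Scenario Land-Use Optimization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled analysis of land-use/land-cover (LULC) change and ecosystem
    service value (ESV) for an arid mountain-oasis-desert river basin.
    Implements equivalent-factor ESV valuation with per-service and
    per-category decomposition, grid aggregation with Jenks natural-breaks
    levels and coefficient-sensitivity analysis; a grey multi-objective
    linear program for 2030 land-use structure under ecological-priority and
    balanced ecological-economic scenarios, with a GM(1,1) grey forecaster
    and an exact vertex-enumeration solver; Markov-chain transition
    estimation and area projection; a patch-generating cellular automaton
    (random-forest suitability, neighbourhood effect, adaptive inertia,
    random patch seeding with a decreasing threshold, and a conversion-rule
    matrix) with overall-accuracy/kappa validation; and grid-level
    trade-off/synergy statistics (Pearson, bivariate global and local
    Moran's I with permutation inference). A synthetic-landscape generator
    provides reproducible desk-scale basins for testing every spatial stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    boot,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
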