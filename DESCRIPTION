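Package: soilwheat
Title: Mechanistic Trace-Metal Transfer and Accumulation in Soil-Wheat Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Compartmental simulator of trace-metal (Cu, Pb, Cd, Ni)
    migration from soil and atmosphere into growing wheat. Couples
    closed-form logistic growth of root, stem, leaf and grain to a linear
    first-order accumulation equation with composed uptake and transfer
    rates, and provides model-verification statistics (root mean square,
    value and fluctuation difference rates), bioconcentration factors,
    lognormal Monte Carlo uncertainty propagation, ordinary-kriging risk
    mapping with three-class prediction-error reporting, and a synthetic
    spatially autocorrelated survey generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
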