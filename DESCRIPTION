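Package: shelfkin
Title: Accelerated Shelf-Life Kinetics for Lipid Oxidation in Low-Moisture Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the loss of sensory quality of low-moisture bakery products
    caused by lipid oxidation. Fits zero-order kinetics of rancid-odor
    development at each storage temperature, pools the rate constants through a
    reparametrized Arrhenius model to estimate the activation energy and the
    frequency factor, regresses the ambient-temperature rate on the peroxide
    value of the ingredient oil, and predicts primary shelf life as a function
    of oil quality and a producer-chosen sensory acceptability limit. Includes
    a simulator for accelerated shelf-life sensory-panel studies on a bounded
    7-point scale with censoring, a ferric-thiocyanate peroxide-value assay
    calculator, reference fixtures from a published cracker storage study, and
    an end-to-end pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
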