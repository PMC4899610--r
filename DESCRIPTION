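Package: clperox
Title: Kinetic Analysis of Cardiolipin Liposome Peroxidation and
    Antioxidant Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts UV absorbance time series from liposome oxidation
    assays into conjugated-diene kinetic traces via Beer-Lambert
    conversion, estimates oxidation rates, induction periods
    (inhibition durations), chain propagation lengths, inhibition
    efficiencies and radical-trapping stoichiometries of chain-breaking
    antioxidants, and provides a mass-action kinetic simulator of
    azo-initiator-driven lipid peroxidation with quinol or chromanol
    inhibition. The simulator doubles as a synthetic-data generator
    reproducing the statistical structure (noise floor, 5-minute
    sampling, delayed antioxidant addition) that the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
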