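Package: hspcompat
Title: Hansen Solubility Parameter Estimation from Swelling Data and
    Migration-Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the Hansen Solubility Parameters (HSP) of insoluble,
    cross-linked polymers from solvent-swelling experiments by constrained
    maximization of the R-squared of the linear relation between Hansen
    distance (Ra) and percent swelling, and screens polymer-food
    compatibility via Ra distances and the Relative Energy Difference
    (RED = Ra/Ro) against grouped food-component HSP databases. Includes
    uncertainty propagation (delta method and Monte Carlo), multi-polymer
    comparison, a synthetic-data generator for parameter-recovery studies,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
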