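Package: cropmix
Title: Bio-Economic Optimisation of Arable Crop Mixes Under Reduced Tillage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-farm bio-economic model for combinable-crop systems
    under tillage regimes of decreasing intensity (conventional ploughing,
    rotational ploughing, deep and shallow reduced tillage, zero tillage).
    Computes per-hectare gross margin, net energy and greenhouse-gas
    coefficients for crop activities (crop variant x straw fate x nitrogen
    level), optimises the farm crop mix by linear programming under
    steady-state rotation, work-period resource and CAP-Greening
    constraints, converts solutions into whole-farm net margin with
    usage-dependent machinery depreciation, and drives scenario analyses
    including yield-penalty breakeven search, black-grass herbicide costs,
    spring-barley selection sweeps and alternative price years.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
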