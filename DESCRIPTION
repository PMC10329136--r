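Package: nescoast
Title: Coastal Sustainability Assessment with Coupling Coordination and
    Spatial Heterogeneity Detectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score coastal sustainable development from hierarchical
    natural-economic-social indicator panels. Implements three-tier composite
    scoring with min-max normalization and configurable or entropy weights,
    the three-subsystem coupling-coordination degree model, exact Fisher-Jenks
    natural-breaks classification, global Moran's I with permutation inference
    on configurable spatial weights, and the geographical detector (factor
    q-statistic with noncentral-F or permutation significance, and the
    five-category interaction detector). Ships a synthetic country-panel
    generator with known spatial clustering and driver structure so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
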