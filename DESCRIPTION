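Package: scprank
Title: Spatial Conservation Prioritization and Protected-Area Gap Analysis
    on Gridded Landscapes
Version: 0.1.0
Authors@R:
    person("scprank", "developers", email = "scprank@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing how well a protected-area network represents
    a pool of species, and for ranking landscape cells to guide network
    expansion. Implements an additive-benefit-function greedy cell-removal
    prioritizer with cost weighting, boundary-length penalty, edge removal
    and forced inclusion of existing protected areas; conversion of
    continuous habitat-suitability surfaces to binary ranges via the
    10th-percentile training-presence threshold; spatial-block
    cross-validation folds with presence-background AUC and TSS; a
    range-size-dependent well-represented criterion for gap analysis; and a
    virtual-species landscape simulator so the full pipeline is testable
    without any external data. Rasters are read and written as plain-text
    ESRI ASCII grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
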