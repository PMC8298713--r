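Package: cellpursuit
Title: Detecting Long-Range Interactions Between Migrating Cells from
    Trajectory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection of long-range (chemotactic) interactions
    between two classes of tracked cells, such as natural killer cells hunting
    tumor cells in a collagen gel.  Each movement step of a migrating cell is
    scored against a null model of blind migration (Rayleigh step widths, von
    Mises turning angles) by integrating the turning-angle density over the
    "approach cone" of directions at least as target-oriented as the observed
    step.  The pooled p-value histogram is compared to a confidence band built
    from ensembles of target-randomized reference data sets, yielding an
    attraction/repulsion verdict.  Includes an agent-based simulator of four
    chemotaxis scenarios (blind search, random mode switching, temporal and
    spatial gradient sensing) with a chemoattractant field, killing radius and
    target depletion, used to validate the detection pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    MASS,
    optparse
Config/testthat/edition: 3
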