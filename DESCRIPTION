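Package: cohortflow
Title: Longitudinal Cancer-Cohort Block Views, Sankey Flows and
    Feature-Variability Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data model and scriptable toolkit for exploring longitudinal
    cancer cohorts in which each patient contributes several timepoint
    samples plus dated clinical events (e.g. treatments). Builds alternating
    timepoint/event block grids with flexible alignment, supports feature
    transforms (binning, log scaling, Boolean and gene-set combination,
    ordinal conversion), scores feature variability within and across
    timepoints (ModVR, coefficient of unalikeability, coefficient of
    variation, variance, rate of change) and ranks features; computes
    grouped proportion blocks and Sankey flows between adjacent blocks;
    reads and writes cBioPortal-style clinical, timeline and MAF files;
    generates seeded synthetic cohorts with known ground truth; and renders
    deterministic static block-view and timeline figures to SVG/PNG/PDF.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
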