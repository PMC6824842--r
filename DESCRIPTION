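Package: dropsurv
Title: Microdroplet Segmentation and Bacterial Survival Statistics on Drying Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and statistical pipeline for quantifying microscopic
    surface wetness on drying surfaces: segmentation of microdroplets from a
    fluorescence channel by combined intensity and gradient thresholds, live/dead
    cell segmentation from green/red channels, assignment of cellular objects to
    host droplets, power-law droplet-size distribution fitting (log-binned least
    squares and truncated maximum likelihood), survival-versus-droplet-size
    statistics, logistic models of the relative contribution of droplet and
    aggregate size to survival, and fluorescence-based estimation of solute
    concentration via piecewise-linear calibration curves. Includes a seeded
    synthetic-scene generator that renders multi-channel 16-bit micrographs with
    known ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    glmnet,
    igraph,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
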