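Package: flycourt
Title: Automated Recognition of Drosophila Courtship Behavior from Backlit Arena Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An image-processing pipeline for scoring male fruit-fly courtship in
    backlit circular arenas. Segments flies from the background with a spatial
    maximum filter, splits silhouettes into wings and torso, characterizes per-fly
    pose (position, heading, wing-extension angles, torso eccentricity), maintains
    male/female identities through full overlaps by spectral clustering and
    watershed-based torso shape matching, classifies five courtship elements per
    frame (orientation, tapping, singing, attempted copulation, copulation) with a
    temporal noise filter, and aggregates labels into courtship time, element
    proportions, and behavioral transition matrices. Ships a parametric synthetic
    scene renderer with full ground truth so the whole pipeline is testable without
    recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
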