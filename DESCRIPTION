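Package: spheromorph
Title: Automated Morphometric Profiling of 3D Spheroid Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation and morphometric quantification of multicellular
    spheroid structures in low-magnification fluorescence or phase-contrast
    images of three-dimensional organotypic cultures. Implements intensity
    projection of confocal stacks, histogram-valley thresholding, gap
    filling, distance-transform watershed labeling with a user-tunable
    sensitivity, substructural (per-channel) cell segmentation, and a
    catalogue of per-structure shape, appendage, neighborhood and channel
    parameters. A screen-statistics layer provides standardized
    median-difference heatmaps with Bonferroni-corrected Mann-Whitney
    filtering, Spearman parameter-correlation maps, complete-linkage
    clustering, and well/position variance-component quality control.
    Includes a seeded synthetic-field generator with exhaustive ground
    truth and a batch command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jpeg,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
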