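Package: hestain
Title: Virtual H&E Staining of Fluorescence Microscopy by Neural Style Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms grayscale confocal laser endomicroscopy (CLE) micrographs
    into images with the appearance of hematoxylin and eosin (H&E) histology using
    neural style transfer: Gram-matrix style representations and a deep-layer
    content representation are extracted with a convolutional backbone, and the
    target image's pixels are optimized by L-BFGS to minimize a weighted
    content-plus-style loss. Includes the color-coding post-processing used to
    control for color-resemblance bias in expert rating (gray, green-only,
    red-only, intact), a dual-axis 0-6 rater-score data model with histogram,
    score co-occurrence (intensity) map, modal score combinations, one-way
    chi-square and paired t statistics, per-image improvement categories, and
    seeded synthetic generators for pseudo-CLE content images, a pseudo-H&E style
    image, and rating tables with planted statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
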