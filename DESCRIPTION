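Package: rootridge
Title: Root Diameter Distributions from Images of Excavated Storage-Root Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the root-diameter distribution of excavated storage-root
    crops (cassava and similar species) from single images or rotating-root
    image sequences taken in front of a blue background. Segments the root
    system by colour, blur and label masks, locates root centerlines with an
    iterative multi-scale Steger-style ridge detector that measures a local
    width at every centerline pixel, and converts the result into constituent
    lengths per diameter class (<2, 2-6, 6-20, >20 mm). Includes a synthetic
    root-image generator with analytic per-diameter-class ground truth and a
    validation harness (regression statistics, mask metrics, a perspective
    shortening model) for simulation-based accuracy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
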