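Package: fiberquant
Title: Quantification of Denervation-Induced Muscle Fiber Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image and expression analysis toolkit for skeletal muscle
    remodeling after denervation. Implements the 2D mitochondrial network
    orientation pipeline (edge-preserving bilateral filtering, Otsu fiber
    segmentation, multiscale Frangi vesselness enhancement, fiber-axis-relative
    angle binning), 3D mitochondrial volume and shape morphometry with
    distribution comparison, nuclear-to-cytoplasmic intensity ratio
    quantification with nested per-muscle aggregation, neuromuscular-junction
    endplate morphometry with dual-label acetylcholine-receptor turnover by
    pixel dominance, and classification of genes from three differential
    expression contrasts into activity-dependent and -independent classes.
    A seeded synthetic-data module generates every input class with exact
    ground truth for validation.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
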