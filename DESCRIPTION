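Package: wheatpheno
Title: Wheat Plant Phenotyping from Colored 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for extracting phenotypic traits of potted
    wheat plants from colored 3D point clouds such as those produced by
    multi-view stereo reconstruction. The package restores real-world scale
    from a marker sticker of known width and levels the frame against a
    RANSAC-fitted ground plane, isolates the plant with a centroid-cutoff
    Euclidean clustering step followed by green-color and statistical outlier
    filtering, segments stems and leaves by region growing on surface normals
    and curvature, and measures plant height, crown area, convex-hull volume,
    ball-pivoting surface area, and per-leaf midrib length and width. A
    procedural wheat-scene simulator with exact ground truth, accuracy metrics
    (R2, RMSE, relative RMSE), one-way ANOVA summaries and growth-dynamics
    reports support validation across the six wheat growth stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
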