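Package: seedshape
Title: Seed Shape Quantification with Geometric Models and the J Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the shape of seed silhouettes in dorsal view by
    comparison with a registry of nine geometric models (a superellipse,
    seven two-arc modified ellipses and one polar curve), following the
    J-index approach: the percent of area shared between a seed mask and a
    model after superposition for maximum coincidence, optimized over a
    similarity transform. Also provides ImageJ-convention shape descriptors
    (area, perimeter, major-axis length, width, aspect ratio, circularity,
    roundness), convexity classification by solidity, average-silhouette
    construction for seed populations, a synthetic seed generator with
    known ground truth, plate segmentation, and nonparametric population
    comparison with compact letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
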