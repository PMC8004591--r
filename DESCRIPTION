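Package: leafMorph
Title: Automatic Leaf Segmentation and Morphological Trait Measurement from
    3D Plant Meshes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic measurement of typical leaf samples on
    triangle meshes of potted plants acquired with hand-held 3D laser
    scanners. The package removes non-plant geometry (RANSAC table
    detection plus a 100 mm buffer filter), segments individual leaves by
    multi-level region growing with thresholds adapted to the mesh's own
    smoothness and curvature statistics, filters the segments down to
    typical leaf samples with two PCA-weighted leaf shape models (a size
    model on area/perimeter/length/width and an architecture model on
    their six ratios), and reports ten morphological traits per leaf.
    Includes scanning/segmentation accuracy ratios, modeling efficiency,
    RMSE and MAPE statistics, and a procedural generator of scanner-like
    plant scenes with a ground-truth ledger for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
biocViews: Software, Visualization, Phenotype, Segmentation
RoxygenNote: 7.3.3
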