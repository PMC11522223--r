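Package: rotomorph
Title: 3D Reconstruction and Morphometric Phenotyping of Rotating C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a brightfield frame sequence of a specimen rotating
    uniformly about a horizontal axis into a dense 3D model by
    shape-from-silhouette visual-hull carving, validates the model by
    reprojection intersection-over-union, and extracts five 3D morphometric
    phenotypes (surface area, volume, length, maximum width, length-to-width
    ratio) with downstream group statistics (two-group t tests and PCA-based
    strain classification). A parametric phantom generator renders rotation
    image stacks of synthetic adult worms and embryos with analytic ground
    truth, standing in for the robotic rotation rig and microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
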