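Package: endowarp
Title: Mask-Guided Warping Augmentation for Cell-Mosaic Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data augmentation for segmentation of cell-mosaic microscopy
    images such as the corneal endothelium. Keypoints are extracted from a
    segmentation mask (cell centroids plus a fixed border lattice), perturbed
    by distance-scaled uniform random shifts, and image and mask are warped
    jointly through piecewise local affine transforms over a Delaunay
    triangulation. Warped masks are repaired with marker-based watershed
    refinement. Includes a synthetic endothelium-mosaic generator with
    ground-truth labels, segmentation agreement metrics (Dice, accuracy,
    mean IoU), a batch augmentation pipeline with reproducibility sidecars,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    interp,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
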