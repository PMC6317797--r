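Package: devomap
Title: Developmental Growth Maps of Embryonic Rudiments by Deformable Image Registration
Version: 0.1.0
Authors@R: person("Devomap", "Maintainers", email = "devomap@example.org", role = c("aut", "cre"))
Description: Builds averaged three-dimensional developmental maps of growth
    displacement from pairs of volumetric images of embryonic skeletal
    rudiments at two developmental stages. Implements the full protocol:
    single-level threshold segmentation with largest-component retention,
    mask erosion, bounding-box cropping, Lanczos resampling, centre-of-mass
    plus mutual-information rigid pre-alignment, a grid-based deformable
    registration engine with an intensity-offset term, Laplacian smoothness
    regularisation and coarse-to-fine nodal spacing, grid-cell filtering
    against the early-stage mask, averaging of pairwise displacement fields
    into developmental and single maps, hexahedral mesh morphing with
    surface-node extraction, and shape comparison metrics (Hausdorff and
    Modified Hausdorff Distance, Average Displacement Difference) with
    precision and repeatability summaries. A parametric phantom generator
    provides synthetic two-lobed rudiment volumes with known ground-truth
    growth fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
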