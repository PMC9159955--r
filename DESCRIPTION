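Package: skintrace
Title: Longitudinal Two-Photon Imaging Pipeline for Cutaneous Sensory-Fiber
    Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking degeneration and regrowth of cutaneous
    sensory nerve fibers across months of in-vivo multiphoton imaging.
    Implements the full processing chain for quadrant-tiled 16-bit image
    stacks of glabrous skin: feature-based tile stitching, semi-supervised
    graph segmentation and removal of epidermal autofluorescence and skin
    appendages, depth-adaptive 16-to-8-bit conversion, rigid (trimmed
    iterative closest point) plus thin-plate-spline registration of imaging
    sessions, 3D fiber tracing into geometric graphs with gap bridging and
    caliber classification, and structural-plasticity quantification (total
    fiber length, fiber endings, intra-epidermal free endings, percent of
    baseline, gained and lost segments). Includes a ground-truthed synthetic
    skin-innervation simulator for validation: tubular fiber forests of two
    caliber classes, epidermal autofluorescence with hair-like clutter,
    depth-dependent excitation gain, Poisson and Gaussian noise, four-tile
    acquisition geometry and longitudinal denervation/reinnervation change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
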