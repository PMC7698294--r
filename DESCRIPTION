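Package: fibermat
Title: Voxel Fiber-Network Simulation and Porous-Matrix Morphometry
Version: 0.1.0
Authors@R: person("fibermat", "developers", role = c("aut", "cre"),
    email = "fibermat@example.org")
Description: Tools for designing porous cellulose fiber matrices in silico:
    a voxel-based 3D fiber deposition simulator with flexibility-limited
    draping, micrograph-style structure metrics (surface and bulk porosity,
    pore-area and fiber-width distributions via connected components,
    skeletonization and Euclidean distance transforms), Otsu segmentation of
    SEM-like grayscale images, synthetic phantom generation with exact
    ground truth, and a design-of-experiments layer (latin-hypercube sweeps,
    CART regression and classification trees, suitability-window optimum
    selection) for locating porosity and pore-uniformity optima.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
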