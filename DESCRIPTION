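Package: VoroClust
Title: Voronoi Tessellation and Cluster Segmentation for Single-Molecule
    Localization Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of 2D and 3D single-molecule localization
    microscopy (SMLM) point clouds with Voronoi tessellations.  Builds exact
    per-point Voronoi cells from Delaunay one-ring neighbours by brute-force
    bisector clipping, flags cells cut by the dataset bounding volume, and
    segments clusters by thresholding normalized cell sizes at the
    intersection of the experimental cell-size distribution with a null
    model.  Two interchangeable null models are provided: Monte-Carlo
    simulations of uniform point processes (mean distribution plus envelope)
    and closed-form Poisson-Voronoi gamma approximations.  Includes a
    synthetic localization simulator and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deldir
Config/testthat/edition: 3
RoxygenNote: 7.3.3
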