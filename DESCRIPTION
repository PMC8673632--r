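Package: voxelseg
Title: Voxel-Wise Semantic Segmentation of Large 3D Greyscale Volumes
Version: 0.1.0
Authors@R:
    person("Voxelseg", "Developers", email = "voxelseg@example.org",
           role = c("aut", "cre"))
Description: Per-voxel semantic labelling of large 3D greyscale
    (tomography-style) volumes from a sparse set of manually annotated
    slices.  Feature vectors combine the voxel intensity, multi-scale
    neighbourhood intensity histograms computed with an incremental
    O(r^2) sliding-window algorithm, and uniform rotation-invariant
    local binary pattern histograms on three orthogonal planes.
    Classification uses a random forest or a small feed-forward neural
    network, with a two-stage random search over the joint feature and
    hyperparameter space.  Volumes are processed in z-slabs so memory
    stays bounded by the slab, not the volume; I/O supports TIFF slice
    stacks, multi-page TIFF and HDF5.  Includes a synthetic textured
    phantom generator so the full pipeline is testable without any
    external scan data.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
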