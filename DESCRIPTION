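Package: cavlabel
Title: Geometric Characterisation and Hierarchical Labelling of Cerebral
    Arterial Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated anatomical labelling of cerebral arteries
    from binary angiographic volumes. Provides a synthetic Circle-of-Willis
    vascular tree simulator with voxelization; 3D vessel geometry extraction
    (isovoxel resampling, isosurface meshing, topology-preserving
    skeletonisation, pruning, rooted tree construction and radius-annotated
    centerlines); per-spot geometric feature vectors (cross-sectional area,
    inscribed radius, caliper diameters, circumference, tortuosity,
    curvature, circularity) sampled at a fixed centerline interval; a
    hierarchical spot/segment/branch/chunk nomenclature of 62 arterial
    branches grouped into 20 chunks; a two-step multilayer-perceptron
    classifier (spot-to-chunk, then spot-to-branch within chunk) with
    segment-wise majority voting and anatomical post-processing; and an
    evaluation surface with per-class metrics, multiclass ROC/PR areas,
    groupwise feature statistics and cluster-separability checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    igraph,
    nnet,
    jsonlite,
    RNifti,
    ggplot2,
    cluster,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
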