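Package: vafamorph
Title: Morphometry and Rupture-Risk Classification of Fusiform Vessel
    Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometry of fusiform aneurysms of the
    vertebral artery from triangulated vessel surfaces.  The pipeline
    voxelizes a watertight surface mesh, extracts and smooths the vessel
    centerline by 3D thinning and penalized spline fitting, computes
    Frenet-Serret curvature and torsion together with eight
    cross-sectional shape indices along the centerline, detects the
    aneurysm bulge, assembles a named 571-element geometric feature
    vector per case, ranks features by Welch t-tests with correlation
    pruning, and evaluates rupture-risk classifiers (support vector
    machine, random forest, k-nearest neighbours, subspace discriminant)
    under leave-one-out and repeated train/test-split cross-validation.
    A synthetic vessel and cohort generator provides ground-truth
    phantoms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    e1071,
    randomForest,
    MASS,
    class,
    splines,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
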