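Package: foxray
Title: CT-Based Synthetic X-Ray Data Generation for Foreign Object Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns one or a few segmented product CT volumes into large
    labelled sets of artificial single-view X-ray radiographs for training
    foreign-object-detection classifiers. Provides labelled-volume phantom
    generators (clay with pebble stones, layered avocado with air pockets,
    sphere-in-ball), multi-level Otsu segmentation of attenuation volumes,
    affine and cluster-based region-removal deformation models, an exact
    Siddon ray-traced Beer's-law forward projector (parallel and cone beam),
    a mixed Poisson-Gaussian detector noise model with mean-variance
    calibration, dataset assembly with leakage-free train/validation splits,
    and a lightweight gradient-boosted baseline classifier with repeated-seed
    accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    xgboost,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
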