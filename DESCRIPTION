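Package: tomocyte
Title: Label-Free White Blood Cell Profiling from Refractive Index Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry and classification of single white
    blood cells imaged by optical diffraction tomography. Provides readers
    and writers for volumetric refractive index (RI) tomograms, a synthetic
    spheroid phantom generator with exact analytic ground truth, extraction
    of six morphological and biochemical parameters (cellular volume,
    surface area, sphericity, dry mass, protein density, mean RI), a 3D
    convolutional neural network classifier with 2D-projection and
    classical machine-learning baselines, and UMAP visualization of learned
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    MASS,
    e1071,
    rpart,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
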