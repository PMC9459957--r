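Package: phenoscan
Title: Turntable LiDAR Scanning, Reconstruction and Phenotyping of Potted Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for a turntable-based 2D LiDAR plant phenotyping platform:
    a ray-casting scanner simulator with a distance-dependent range-noise model,
    homogeneous-coordinate reconstruction of polar profiles into 3D point clouds,
    planar-target platform calibration, cube-based accuracy and precision
    metrology, point-cloud pre-processing (statistical outlier removal, Z-axis
    cropping), scalar traits (plant height, occupied-voxel volume), and
    stem/leaf organ classification with a Random Forest on local geometric
    descriptors followed by an ascending virtual-ring stem filter. Includes
    readers and writers for flat TXT point clouds, PLY, raw profile CSV and
    calibration JSON, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
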