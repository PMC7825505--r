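Package: orchardcanopy
Title: Mobile LiDAR-Inertial Mapping and Canopy Phenotyping for Orchards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale mobile LiDAR scanning pipeline for orchard
    phenotyping. Simulates ground-truthed orchard scenes (16-beam spinning
    LiDAR plus 400 Hz IMU on a tracked robot), estimates the platform
    trajectory with an iterated error-state Kalman filter fusing IMU
    propagation and LiDAR edge/planar feature matching, assembles a
    gravity-aligned point-cloud map with a rotation-constrained registration
    step, segments individual fruit trees by Euclidean clustering with
    statistical-outlier-removal splitting and nearest-neighbour recovery, and
    extracts per-tree crown height (RANSAC ground plane) and crown volume
    (alpha-shape over a 3D Delaunay tetrahedralisation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
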