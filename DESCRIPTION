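Package: canopycce
Title: Individual Tree Segmentation from LiDAR Point Clouds by Watershed
    and Connection-Center-Evolution Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end individual tree segmentation for airborne and
    UAV laser scanning point clouds. Builds a digital terrain model by
    TIN interpolation of ground points, normalizes heights, generates a
    pit-free canopy height model, performs an initial watershed
    segmentation with tolerance-based merging, then refines each crown
    segment by connection-center-evolution clustering on mean-shift
    voxelized super-points, selecting the clustering scale automatically
    from tri-planar crown projection constraints. Includes tree matching
    and detection/height accuracy metrics, a deterministic synthetic
    forest generator for offline validation, and readers/writers for
    LAS, XYZ, ESRI ASCII grid and TIFF rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
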