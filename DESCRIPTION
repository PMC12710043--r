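Package: phyllo3d
Title: Voxel-Carving Phyllotaxy Phenotyping and Quantitative Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for measuring phyllotaxy (the azimuthal
    arrangement of leaves around the stem) from calibrated multi-view plant
    silhouettes. Generates procedural sorghum-like plants with known leaf
    azimuths, renders turntable silhouettes, carves voxel visual hulls,
    reduces them to skeleton graphs by topology-preserving 3D thinning,
    segments stem and leaves by a path-counting rule, and measures per-leaf
    inclination and azimuth in the stem's principal-axis coordinate frame.
    Downstream tools derive phyllotaxic angle series and their deviations
    from the 180-degree alternating ideal, apply range filters and
    conjugate-angle alignment for repeatability analysis, estimate
    broad-sense heritability from a one-way random-effects model, perform
    marker quality control on biallelic genotype matrices, and run a
    resampling model inclusion probability (RMIP) association scan around a
    pluggable single-marker engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    lme4,
    e1071,
    png,
    vcfR,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
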