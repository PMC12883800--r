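Package: fscchange
Title: Forest Sub-Compartment Vegetation Cover Classification and Change Detection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polygon-level (forest sub-compartment) vegetation cover type
    classification and post-classification change detection from two-epoch
    multispectral imagery. Implements centroid-anchored 5x5 patch extraction,
    spectral band and vegetation-index features, gray-level co-occurrence
    matrix (GLCM) texture metrics, grouped gradient-boosting gain feature
    selection, a particle-swarm-optimized backpropagation neural network
    classifier with random forest, support vector machine and plain BPNN
    baselines, transition-matrix change analysis with retention and
    conversion rates, confusion-matrix accuracy metrics, change detection
    rates against reference changes, and Clark-Evans nearest-neighbor-index
    spatial clustering. Includes a seedable synthetic two-epoch scene
    generator with Voronoi sub-compartment tessellation for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    ranger,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
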