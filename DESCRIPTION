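Package: agbstack
Title: Aboveground Biomass Estimation for Natural Secondary Forests from
    Airborne Laser Scanning and Optical Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An area-based pipeline for estimating forest aboveground
    biomass (AGB) from airborne laser scanning (ALS) point clouds and
    multispectral surface reflectance. Computes plot AGB from
    species-specific allometric power laws, extracts ALS elevation,
    density, intensity and canopy metrics after noise removal, IDW
    terrain modelling and height normalization, derives optical band
    combinations, vegetation indices, GLCM textures and principal
    components after SCS+C topographic correction, fuses the two sources
    through COLI indices built on the best-performing LiDAR variable,
    and fits eight base regression algorithms plus two-layer stacked
    generalization ensembles evaluated by leave-one-out
    cross-validation. A seeded synthetic forest-scene generator with
    known ground truth makes every stage testable end to end, and fitted
    models can be applied per pixel for wall-to-wall AGB mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    nnet,
    randomForest,
    caret
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
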