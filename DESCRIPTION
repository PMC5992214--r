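Package: retinaquant
Title: Quantitative Retinal Biomarkers of Alzheimer's Pathology from Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for retinal immunofluorescence in the 3xTg-AD
    mouse model of Alzheimer's disease: microglia skeleton morphometry
    (branches, endpoints, junctions, arborization and morphological index),
    glial and neuronal density and area-fraction readouts, three-dimensional
    volumetry of amyloid-beta plaques and phospho-tau tangles in calibrated
    confocal z-stacks, and the two-way ANOVA / Holm-Sidak group statistics
    used to compare genotypes across disease stages. Includes a seeded
    synthetic confocal-stack generator with machine-readable ground truth for
    validating every measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
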