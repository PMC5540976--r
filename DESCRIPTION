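Package: orivox
Title: Simulation and Analysis of Fine-Grained Orientation Preference
    Patterns in fMRI Voxels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how visual-orientation information is carried
    by functional MRI voxel patterns in primary visual cortex. Provides a
    log-polar stimulus and retinotopic region-of-interest geometry, a
    synthetic cortical-sheet generator that combines columnar-scale
    orientation maps with coarse radial and vertical biases, a strictly
    positive voxel gain field and block-design BOLD noise, per-subrun GLM
    t-value patterns, training-data-only voxel preference labeling,
    cross-validated linear support-vector-machine decoding under voxel-set
    selections and spatial pattern shifts, a cosine-type preference
    replicability index with participant bootstrap, and group-level
    statistics with tidy report output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    RNifti
Config/testthat/edition: 3
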