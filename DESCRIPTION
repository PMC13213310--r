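Package: adipoRaman
Title: Chemometric Analysis of Raman Hyperspectral Maps of Breast Adipocytes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for chemometric analysis of confocal Raman hyperspectral
    maps of breast-tissue adipocytes. Provides a SummarizedExperiment-based
    container for wavenumber-resolved spectral maps; the standard per-spectrum
    preprocessing chain (iterative polynomial baseline correction, standard
    normal variate normalization, Savitzky-Golay smoothing, zero-offset
    restoration); extended multiplicative scatter correction (EMSC) with
    PCA-derived interference components to neutralize carotenoid resonance
    Raman interference; random-forest ranking of discriminant wavenumbers with
    stratified cross-validation; UMAP embedding with seed-stability selection
    and silhouette evaluation; a synthetic adipocyte-cohort generator for
    validation; and a configuration-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    signal,
    randomForest,
    vegan,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
SystemRequirements: Python (>= 3.8) with numpy and umap-learn on the PATH
    (used for the UMAP embedding step)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
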