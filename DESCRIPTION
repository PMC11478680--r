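Package: chlorospectra
Title: Chlorophyll Content Inversion from Leaf Hyperspectral Reflectance
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating leaf chlorophyll content (mg/g) from
    350-2500 nm reflectance spectra under drought stress. Provides an S4
    container for leaf spectra with per-leaf metadata, a registry of 21
    chemometric preprocessing transforms (derivatives, log and reciprocal
    chains, SNV, MSC and their composites), correlation-based and
    water-window-augmented band selection, Kaiser-rule PCA reduction,
    NIPALS PLS1 regression with seedling-grouped 5-fold cross-validation,
    14 vegetation and water indices, leaf-position-aware model comparison,
    and a synthetic spectra generator emulating a multi-treatment drought
    study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite
Config/testthat/edition: 3
biocViews: Regression, Preprocessing, DimensionReduction
RoxygenNote: 7.3.3
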