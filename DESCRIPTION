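Package: aquaferm
Title: NIR and Aquaphotomics Monitoring of Probiotic Juice Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for tracking probiotic fermentation of
    fruit juices from near-infrared transmission spectra in the first
    overtone region of water (1300-1600 nm). Provides a seeded simulator of
    the full fermentation experiment (pH and cell-count trajectories,
    water-band spectra with multiplicative scatter and replicate/scan
    noise), spectral pretreatments (Savitzky-Golay smoothing and
    derivatives, detrending, MSC, SNV, group averaging, difference
    spectra), PCA-LDA classification of fermentation time with grouped
    three-fold cross-validation and principal-component selection, NIPALS
    partial least squares regression of pH and log cell count with
    latent-variable selection, and aquagram computation on the twelve
    water matrix coordinates, including difference aquagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate.R'
    'spectra-io.R'
    'preprocess.R'
    'chemometrics-pca.R'
    'chemometrics-lda.R'
    'chemometrics-pls.R'
    'aquagram.R'
    'pipeline.R'
    'utils.R'
    'aquaferm-package.R'
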