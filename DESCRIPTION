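Package: irdesc
Title: Infrared Spectral Descriptors for Catalytic Reaction Yield Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds fixed-length ligand descriptors from discrete infrared
    (IR) peak-list spectra by k-means binning of the wavenumber axis, with
    intensity-based (IntIR) and wavenumber-based (WaveIR) variants and
    explicit empty-cluster fallback rules. Assembles reaction feature
    matrices (descriptor block plus one-hot bases and solvents plus numeric
    concentration and temperature), evaluates yield-prediction models with
    nested leave-one-group-out cross-validation over a registry of nine
    regressors, and reports per-ligand deviation diagnostics. Includes a
    synthetic generator of peak-list spectra and reaction tables with known
    ground truth, an exact dynamic-programming oracle for one-dimensional
    clustering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    glmnet,
    e1071,
    ranger,
    xgboost,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'spectra.R'
    'clustering.R'
    'descriptors.R'
    'reaction.R'
    'regressors.R'
    'evaluation.R'
    'diagnostics.R'
    'synthetic.R'
    'cli.R'
    'irdesc-package.R'
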