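Package: RDCrank
Title: Alignment Tensor Fitting and Configuration Ranking from Residual
    Dipolar Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the relative configuration of small organic
    molecules from one-bond C-H residual dipolar couplings (RDCs). Fits
    Saupe alignment tensors by singular value decomposition to single
    conformers and to population-weighted conformer ensembles sharing one
    tensor (with optional population optimization), evaluates
    trajectory-averaged RDCs from conformational ensembles, scores
    candidate stereoisomers with the Cornilescu Q factor, per-coupling
    error-normalized deviations and the aggregate n/chi-squared quality
    factor, and ranks candidates with outlier-based falsification against
    maximum error estimates. Includes the published coupling table of a
    seven-stereocenter quinolizidine alkaloid as a worked example and
    seeded synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    withr,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'coupling-data.R'
    'fixtures.R'
    'stereo-enum.R'
    'geometry.R'
    'io-structures.R'
    'alignment.R'
    'quality.R'
    'ensemble-eval.R'
    'ranking.R'
    'synthetic.R'
    'RDCrank-package.R'
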