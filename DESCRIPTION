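Package: mirpls
Title: Mid-Infrared PLS Calibration of Ethanol in Fermented Beverages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of ethanol in fermented beverages from
    attenuated-total-reflectance mid-infrared spectra (1200-850 cm-1) by
    partial least squares regression. Provides spectral input/output
    (CSV and JCAMP-DX), the standard chemometric pre-treatment chains
    (minimum subtraction, min-max normalization, Savitzky-Golay
    derivatives, mean centering), a NIPALS PLS1 engine with
    leave-one-out cross-validation and parsimonious latent-variable
    selection, PCA-based outlier screening, pre-treatment model
    comparison, spike-recovery and method-comparison statistics, an
    internal-standard GC-FID calibration with limits of detection and
    quantification, and a Beer-Lambert mixture-spectrum simulator that
    emulates a 25-standard calibration design so the whole workflow runs
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    lhs,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'gc.R'
    'metrics.R'
    'mirpls-package.R'
    'spectra-io.R'
    'preprocess.R'
    'pls.R'
    'simulate.R'
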