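Package: fmricnr
Title: Signal-to-Noise and Contrast-to-Noise Ratios for fMRI Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for computing and comparing the signal-to-noise (SNR) and
    contrast-to-noise (CNR) ratio definitions in common use for fMRI time
    series. Generates stimulus designs (block, event-related, two-condition
    contrast), convolves them with a canonical haemodynamic response
    function, computes six SNR/CNR definitions and the analytic conversions
    between them, estimates general-linear-model detection power by Monte
    Carlo simulation, and regenerates reference tables linking each
    definition to power. Also provides voxelwise temporal-SNR maps and
    ROI-based CNR estimation for 4D NIfTI volumes, together with a seeded
    synthetic-volume generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, RNifti
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'metrics.R'
    'designs.R'
    'volumes.R'
    'power.R'
    'cli.R'
    'fmricnr-package.R'
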