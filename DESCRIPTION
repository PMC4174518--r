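Package: dhmwound
Title: Quantitative Phase Imaging Analysis of Epithelial Wound Healing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative phase imaging of epithelial wound
    healing assays with digital holographic microscopy (DHM). Simulates
    off-axis holograms, reconstructs wrapped phase by Fourier sideband
    demodulation, unwraps it, and converts phase maps into cellular dry
    mass, mean thickness and layer volume via the refractive increment.
    Fits a spherical-cell phase model to suspended single cells to recover
    integral refractive index, radius, volume and dry mass, and turns
    wound-assay time-lapse stacks into cell-covered area, dry mass,
    thickness and volume series with per-minute rate constants. Includes a
    synthetic-data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
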