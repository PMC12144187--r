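Package: PSHGtools
Title: Pixel-Based Analysis of Polarization-Resolved Second Harmonic
    Generation Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for polarization-resolved second harmonic generation
    (PSHG) microscopy of fibrillar collagen and other non-centrosymmetric
    structures. Implements per-pixel Fourier-series fitting of the PSHG
    intensity profile, algebraic recovery of fiber orientation and the
    second-order susceptibility ratios chi15/chi31 and chi33/chi31, the
    effective alpha-helix pitch angle of the harmonophores, and image-level
    statistics (mode values, orientation-distribution Gaussian width, fiber
    density). A synthetic phantom generator renders polarization stacks with
    known per-pixel ground truth, emulating collagen gel matrices of varying
    type I/III composition and healthy versus scarred skin architecture, so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, ImageAnalysis, Microscopy, Preprocessing
RoxygenNote: 7.3.3
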