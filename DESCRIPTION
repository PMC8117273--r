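Package: cmrs
Title: Processing and Quantification of Cardiac Proton MR Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-voxel cardiac proton magnetic resonance
    spectroscopy (1H-CMRS): simulation of multi-channel free-induction-decay
    (FID) series with breathing-induced shot-to-shot corruption, automatic
    phasing, SVD coil combination, frequency realignment and apodization,
    two-stage retrospective gating of free-breathing averages, time-domain
    linear-combination model fitting of creatine, trimethyl-amide and
    triglyceride resonances with Cramer-Rao lower bounds,
    relaxation-corrected water-referenced quantification (including the
    chemical-shift-displacement and fat-water phantom geometry calculators),
    and test-retest repeatability statistics (Bland-Altman, intraclass
    correlation, linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
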