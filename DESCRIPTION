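Package: arnav
Title: Augmented-Reality Surgical Navigation: Registration, Projector
    Calibration, Tracking Simulation and Accuracy Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a projector-based augmented-reality
    surgical navigation (AR-SN) system. Provides rigid 3-D transforms and
    frame chaining, paired-point fiducial registration with fiducial
    registration error (FRE), pivot calibration of tracked pointers,
    pinhole calibration of a tracked pico-projector by the normalized
    direct linear transform, volume image handling (NIfTI I/O, trilinear
    resampling, threshold segmentation, iso-surface extraction,
    multimodality slice fusion, normalized-mutual-information rigid
    registration), a simulated infrared optical tracker with marker-level
    noise, a software virtual-camera renderer with z-buffering, and an
    in-silico checkerboard-phantom protocol that measures projection
    accuracy as a function of projector standoff distance. All hardware is
    replaced by seeded simulation; synthetic mouse-like multimodality
    volumes and machined-phantom geometry are generated in code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
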