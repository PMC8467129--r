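Package: sfdi
Title: Spatial Frequency Domain Imaging Calibration and Optical Property Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for spatial frequency domain imaging (SFDI)
    with a structured-light projector and camera: sinusoidal pattern generation
    with inverse-perspective keystone pre-correction, fringe frequency
    calibration against a checkerboard scale, three-phase amplitude
    demodulation with whiteboard reflectance calibration, inversion of the
    diffusion-approximation reflectance model to per-pixel absorption and
    reduced scattering coefficient maps, liquid-phantom reference optical
    properties (Beer-Lambert absorption and Mie-theory reduced scattering)
    with linear system correction, a seeded acquisition simulator, and linear
    discriminant classification of fruit surface damage from optical property
    maps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
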