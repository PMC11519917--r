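Package: framestraddle
Title: Lifetime-Proportional Luminescence Imaging by Camera Frame Straddling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward model, timing design, and image-processing pipeline for
    frame-straddling luminescence imaging of oxygen optodes. A pulsed
    excitation source is synchronized with a double-frame camera so that the
    first frame truncates the phosphorescence decay while the second frame
    integrates it completely; the normalized difference of the two frames is
    proportional to the luminescence lifetime and, through the Stern-Volmer
    relation, reports oxygen as percent air saturation. The package provides
    closed-form frame integrals with carry-over, pulse-length optimization
    against a camera noise model, per-pixel calibration and inversion, a
    rapid-lifetime-determination estimator, a synthetic scene renderer for
    validation, and a minimal two-pass FFT cross-correlation PIV for combined
    chemical imaging and velocimetry (sensPIV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
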