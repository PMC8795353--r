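Package: protonflash
Title: Laser-Driven Proton FLASH Radiobiology Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for ultra-high instantaneous dose rate proton
    radiobiology experiments at a laser-driven beamline: exponential proton
    source spectra, continuous-slowing-down energy loss through absorber
    stacks, simplified chromatic-lens beam transport and time-of-flight bunch
    duration; radiochromic-film dosimetry (netOD-to-dose calibration, LET
    quenching and absorber corrections, crescent-shadow exclusion, dose-rate
    arithmetic); automated colony counting from plate photographs via
    Hessian dark-elliptic-feature detection in Gaussian scale space with
    well-ellipse segmentation; and background-corrected clonogenic survival
    with orthogonal-distance-regression fitting of the linear-quadratic
    survival model. A synthetic-data module generates every input with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
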