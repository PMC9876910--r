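Package: hipcal
Title: Bi-Planar Radiograph Calibration for Hip-Plane Magnification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Patient-individual calibration of the hip-plane magnification
    factor for digital templating in total hip arthroplasty from one
    antero-posterior and one lateral radiograph with a single spherical
    calibration marker. Implements the closed-form sphere-projection
    height equations with fixed-point recalibration of the projected
    marker displacement, estimation and correction of patient rotation
    and marker lateral offset, the intercept-theorem conversion between
    object height and magnification factor, a standard-model simulation
    of uncorrected rotation/offset error, and an exact pinhole forward
    projector used as a synthetic-data generator and geometric oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
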