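Package: nirdose
Title: Single-Cell Dose-Response Analysis for Dual-Wavelength Gradient
    Near-Infrared Laser Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput single-cell dose-response imaging with
    orthogonal gradient near-infrared laser beams. Calibrates per-pixel
    dual-wavelength irradiance maps from beam-profile line scans by
    least-squares polynomial fitting with AIC degree selection and
    delta-method confidence bands; detects individual fluorophore-loaded
    cells as smoothed local intensity maxima, links them across time-lapse
    frames by positional stability, and computes per-cell fold changes
    against the pre-illumination baseline; bins cells into irradiance
    combination groups and compares groups against a no-laser control with
    one-way ANOVA followed by Tukey's multiple comparison test. A seeded
    synthetic-scene generator renders Gaussian point-spread-function cells
    on noisy camera frames with known ground truth so the entire pipeline
    can be exercised and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
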