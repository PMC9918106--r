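Package: dermspectra
Title: Hyperspectral Narrow-Band Imaging and Detection Evaluation for Dermoscopy
Version: 0.1.0
Authors@R: person("dermspectra", "maintainers", email = "maintainers@dermspectra.dev", role = c("aut", "cre"))
Description: Reconstructs 401-band (380-780 nm, 1 nm step) reflectance cubes
    from 8-bit RGB dermoscopy images via a PCA spectral basis and polynomial
    regression on tristimulus coordinates, synthesizes narrow-band images from
    hemoglobin-absorption wavelength windows (405-435 and 525-555 nm), ranks
    wavelength bands by between-class separation of lesion spectra, prepares
    annotated datasets (640x640 canvas, Pascal-VOC XML to YOLO txt, stratified
    80/20 split), evaluates detections through a background-aware extended
    confusion matrix with five metrics, and provides reference implementations
    of the GIoU, confidence and classification loss terms used by one-stage
    detectors. Ships a synthetic forward simulator (class reflectance spectra,
    rendered lesion scenes, calibration sets, confusion-matrix-realizing
    detection sets) so the full pipeline is testable without real image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
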