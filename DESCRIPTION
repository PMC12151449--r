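Package: imuconfig
Title: Recording-Configuration Trade-Offs for Multi-Sensor IMU Movement
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how inertial measurement unit (IMU)
    recording configurations (sensor placement, modality, sampling
    frequency) affect second-by-second posture and movement
    classification of freely moving infants, and recording-level
    derivatives thereof (category distributions and a Gaussian-process
    motor maturity score). Includes a calibrated semi-Markov generator
    of synthetic multi-sensor recordings with multi-annotator interval
    labels, zero-phase Butterworth preprocessing, a dilated temporal
    convolutional classifier with cross-validated training, compound
    confusion-matrix agreement statistics (Cohen kappa, recording-level
    bootstrap, paired t tests), and an experiment driver for
    configuration grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
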