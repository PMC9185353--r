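Package: speedcuts
Title: Accelerometer Count Cut-Points for Walking Speed Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibration and application of activity-count cut-points that
    separate non-ambulation from walking and classify walking-speed
    categories (0.41-0.8, 0.81-1.2, >1.2 m/s) from waist- and ankle-worn
    tri-axial accelerometers, as used in post-stroke gait research. Provides
    an open emulation of the count digitization chain (band-pass filter,
    rectification, dead-band, quantization, epoch aggregation, vector
    magnitude), trial segmentation with steady-state trimming, ROC-based
    cut-point selection by the closest-to-corner criterion with AUC grading,
    a classifier preloaded with published cut-point tables, a synthetic
    cohort generator calibrated to published class-conditional count
    medians, and study-style summary reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
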