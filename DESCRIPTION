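Package: stereovibro
Title: Stereo Video Vibrometry for Three-Dimensional Vibration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts sub-pixel two-dimensional motion traces from pairs of
    synchronized high-speed grayscale videos using phase-based video
    vibrometry (oriented quadrature filter pyramids), fuses them through a
    calibrated pinhole stereo model into three-dimensional displacement
    traces, and derives vibration analytics such as axis projection,
    windowed time-domain power, event detection, and wave-speed estimates.
    Includes a pinhole-camera calibration routine based on epipolar-row
    anchoring and exhaustive grid search, and a synthetic stereo scene
    renderer that provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    pracma,
    rlang,
    signal,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
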