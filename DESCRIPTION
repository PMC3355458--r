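Package: skitech
Title: Technique Classification and Asymmetry Analysis for Trunk-Mounted
    IMU Recordings of Cross-Country Skiing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing six-channel inertial measurement unit
    (IMU) recordings (tri-axial accelerometer in g, tri-axial gyroscope in
    degrees/second, 100 Hz) collected from a unit mounted on a skier's
    upper back. Provides a synthetic-signal generator for the seven major
    cross-country skiing sub-techniques (classical: double pole, kick
    double pole, diagonal stride; skating gears G2-G5), zero-phase
    Butterworth low-pass preprocessing, tap-marker synchronisation,
    movement-cycle segmentation with left/right side labelling, extraction
    of the discriminative per-cycle signature features, a rule-based
    technique classifier with a full evidence trail, and a left/right
    limb-symmetry index for kick asymmetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
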