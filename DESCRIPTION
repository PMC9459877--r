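Package: gaitsva
Title: Gait Analysis with Clothing- and Body-Mounted Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing walking with synchronized six-axis inertial
    measurement units worn on the lower body and mounted in everyday loose
    clothing. Implements sensor-to-segment alignment from standing and
    sagittal-plane movements, quaternion orientation estimation with a
    gated Madgwick filter, the sensor-to-vertical angle (SVA), gait-cycle
    extraction from mid-swing acceleration peaks and shank gyroscope minima
    (initial contact and toe-off), and per-cycle agreement statistics
    between clothing- and body-mounted sensor pairs. Includes a synthetic
    multi-sensor gait-session generator with known ground-truth kinematics,
    mounting misorientations and a fabric-coupling model, so that every
    pipeline stage can be validated without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
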