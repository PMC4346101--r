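Package: quatfall
Title: Quaternion-Based Fall Detection from Waist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Threshold-based fall detection for triaxial accelerometer streams
    from waist-worn wearable devices. A fall is recognised from two features:
    an impact peak in the sum acceleration and a body-rotation angle of about
    90 degrees, obtained by decomposing the rotation between the gravity
    vectors captured before and after the impact into three elementary
    quaternions (tilt to the horizontal plane, azimuthal rotation, tilt back).
    Includes the online detection state machine, an acceleration-only baseline
    detector, a seeded parametric generator of fall and activities-of-daily-
    living waveforms with ground truth, and sensitivity/specificity evaluation
    utilities, plus CSV trace I/O, YAML configuration and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
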