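Package: erkfgait
Title: Multi-IMU Error-State Kalman Filtering for Lower-Limb Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates segment poses and gait kinematics of a three-body
    lower-limb model (pelvis plus two hinged legs) from body-worn inertial
    measurement units using a multi-IMU error-state Kalman filter. Strapdown
    integration of accelerometer and gyroscope data is corrected by four
    kinematic pseudo-measurements: zero-velocity updates, gravitational tilt
    corrections, joint-center coincidence, and hinge joint-axis alignment.
    Includes a synthetic walker-gait simulator that produces ground-truth
    poses, ideal and noisy IMU signals, and event annotations; gait analysis
    tools for hip joint angles (ISB convention), stride length, step width
    and drift diagnostics; and a reproducible simulate-filter-analyze
    pipeline with CSV/YAML/JSON interchange.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
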