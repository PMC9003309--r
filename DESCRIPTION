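Package: walkimu
Title: Self-Calibrating Magnetometer-Free IMU Estimation of Hip and Knee Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lower-body joint kinematics during walking from seven
    body-worn inertial measurement units (gyroscope + accelerometer, no
    magnetometer). Jointly estimates per-sensor pose trajectories and static
    sensor-to-joint-center calibration by sparse nonlinear least squares with
    inertial, joint-center, hinge-axis and prior residuals solved per window
    with Levenberg-Marquardt; derives hip angles in a modified ISB (Wu)
    convention and knee angles in the Grood-Suntay joint coordinate system;
    detects and corrects linear drift of hip internal/external rotation; and
    compares estimated angles against a reference with absolute/relative RMSE,
    peak error, gait-cycle segmentation and gait-phase soft-tissue error
    profiling. Includes a synthetic gait and calibration-motion simulator with
    a rigid-mount inverse sensor model for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
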