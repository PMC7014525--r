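Package: stridespeed
Title: Per-Stride Horse Speed Estimation from a Single Saddle-Mounted IMU
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates canter speed per stride from a single six-channel
    inertial measurement unit (tri-axial accelerometer and gyroscope at
    100 Hz) mounted at the pommel of the saddle. Strides are anchored at
    dorso-ventral acceleration peaks and cut into fixed 6 x 101 windows;
    speed is estimated either by a signal-based baseline (overall dynamic
    body acceleration, ODBA, linearly regressed onto speed) or by
    nu-support-vector regression on the flattened window. Includes the
    full method-comparison protocol (percentage of errors above 0.6 m/s,
    RMSE, Bland-Altman 95% limits of agreement over repeated 80/20
    holdout splits), a synthetic canter-signal generator with known
    ground-truth speeds for both straight-path and curved-path reference
    protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
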