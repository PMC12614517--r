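Package: walksense
Title: Contactless Gait Analysis from Skeleton Streams and Floor Vibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates gait speed and cadence from two contactless modalities
    recorded during hallway walking trials: skeleton joint-position streams
    from a depth camera (pelvis-displacement linear fit with iterative
    R-squared trimming; foot-swing FFT cadence) and multi-channel
    floor-mounted accelerometer records (zero-phase Butterworth
    preprocessing, cross-correlation clock synchronization, adaptive
    SNR-based footstep detection, energy-decay localization and
    constant-speed Kalman tracking). Includes a synthetic walker simulator
    that generates paired modalities with full ground truth, and the
    reliability and validation statistics used to assess such systems:
    intraclass correlation with permutation testing, outlier-screened
    device-versus-stopwatch comparison, leave-one-out logistic prediction,
    frailty grouping and recovery-outcome interaction models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
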