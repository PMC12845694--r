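Package: respgate
Title: Adaptive Kalman Filtering, Prediction and Gating of Respiratory Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for latency-compensated tracking of respiratory
    displacement in image-guided interventions. Provides a harmonic
    state-space adaptive Kalman filter with on-line frequency and noise
    covariance estimation and multi-step-ahead prediction; anticipatory
    end-inspiration gating with template-based dual validation; breathing
    pattern classification (regular / shallow / irregular) from amplitude
    and rhythm irregularity indices; closed-form rigid point-set
    registration of fiducial correspondences; a seeded respiratory waveform
    simulator (sine, regular, shallow and irregular breathing with noise,
    baseline drift and measurement latency); and an evaluation harness for
    target-point error and prompt-timing statistics comparing compensated
    and uncompensated navigation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
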