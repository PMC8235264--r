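Package: qcmdwt
Title: Dual-Resonator Wavelet Correction and Stability Metrics for
    QCM-D Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes correlated environmental and setup disturbances
    (temperature gradients, flow-rate interference, baseline drift,
    electronic noise) from quartz crystal microbalance with dissipation
    monitoring (QCM-D) resonance-frequency and dissipation time series by
    combining a multi-level discrete wavelet transform with dual-resonator
    common-mode cancellation: wavelet-coefficient derivatives of a sensor
    and a co-located reference resonator are compared by a sliding-window
    Pearson correlation test and, where significantly correlated, the
    reference is projected linearly into the sensor space and subtracted.
    Includes the filtered direct-subtraction comparator, resonator
    stability metrics (Allan deviation, baseline drift rate, baseline
    noise, Sauerbrey mass sensitivity, instrument detection limit), a
    synthetic paired-signal generator with ground truth for validation,
    CSV trace input/output, and a block-wise streaming mode for real-time
    use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
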