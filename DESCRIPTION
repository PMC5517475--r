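Package: aiscope
Title: Active-Illumination Multiphoton Microscopy Simulation and
    High-Dynamic-Range Log-Encoded Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and analysis toolkit for active-illumination
    multiphoton microscopy, in which per-pixel negative feedback regulates the
    excitation power so the detected fluorescence holds a set point, and the
    sample strength X = S / P^alpha is log2-encoded onto standard acquisition
    electronics.  Provides seeded synthetic structural scenes and calcium-
    imaging movies, a physical model of excitation, shot noise, detector
    saturation and power measurement, a discrete PID feedback loop with
    automatic switching between feedback-active and power-limited modes,
    the fixed-point log2 encoder and its post-hoc linear reconstruction,
    closed-form and Monte-Carlo signal-to-noise analysis, dynamic-range
    accounting, and dF/F0 functional-response statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
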