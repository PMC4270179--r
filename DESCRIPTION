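Package: burstkit
Title: Quantification and Comparison of EEG Burst Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying electroencephalogram (EEG) burst
    suppression and comparing it between anesthetic conditions. Segments
    single-channel EEG into bursts and suppressions with the nonlinear
    energy operator and an energy-domain threshold, estimates the burst
    suppression ratio (BSR) and the burst suppression probability (BSP)
    with a Bernoulli state-space smoother fitted by expectation
    maximization, extracts per-event duration, peak-to-peak amplitude and
    power features binned by BSP level, and performs percentile-bootstrap
    median-difference inference between two conditions. Includes multitaper
    spectrograms, a minimal EDF reader/writer, and a seeded synthetic
    burst-suppression EEG generator with drug-specific profiles and known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
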