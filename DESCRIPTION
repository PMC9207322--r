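Package: ergdwt
Title: Discrete Wavelet Transform Analysis of the Flash Electroretinogram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-frequency analysis of light-adapted flash
    electroretinogram (ERG) waveforms with the Haar discrete wavelet
    transform. Provides a synthetic cohort simulator for flash-ERG epochs
    with controllable group effects, trace averaging with centile-based
    sweep rejection, quality-control filtering, an orthonormal Haar DWT
    with scalogram construction, band/window energy descriptors (a20, a40,
    b20, b40, op80, op160 and the oscillatory-potential percentage),
    time-domain a- and b-wave measurement, and nonparametric group
    comparisons via Tukey-type multiple contrast tests on relative effects
    with simultaneous confidence intervals, plus classical rank tests and
    the robust percentage-bend correlation. A pipeline assembles these
    stages into a per-flash, per-parameter results table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite,
    readr,
    tibble,
    dplyr,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
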