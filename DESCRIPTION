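Package: gtdose
Title: Dicentric Chromosome Biodosimetry with a Gompertz-Type
    Weighted-Poisson Dose-Response
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cytogenetic dose estimation from dicentric chromosome counts
    over the full 0-25 Gy range. Implements an underdispersed two-parameter
    weighted Poisson distribution for dicentrics per cell, a four-parameter
    Gompertz-type (GT) dose-response calibration fitted by maximum
    likelihood on cell-level count distributions, and classical linear and
    linear-quadratic Poisson calibrations for comparison. Whole-body doses
    are estimated by inverse regression with Merkle-style confidence
    limits that combine calibration-curve and observed-yield uncertainty;
    partial-body doses via a zero-truncated weighted-Poisson fit of the
    irradiated fraction or the classical Dolphin contaminated-Poisson
    method. Includes dispersion diagnostics (u-test), goodness-of-fit
    statistics, simulation of whole- and partial-body exposures, a plain
    TSV interchange format for dicentric distribution tables, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
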