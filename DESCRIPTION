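Package: hrvaf
Title: Heart-Rate-Variability Screening of Postoperative Atrial
    Fibrillation Risk from Hourly RR-Interval Segments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to read, clean and segment beat-to-beat RR-interval
    recordings, compute linear (SDNN, RMSSD, pNN50) and nonlinear
    (Poincare SD1/SD2, normalized delta-RR dispersion, Lomb-Scargle
    LF/HF band power) heart-rate-variability descriptors, and classify
    hourly segments into three atrial-fibrillation risk classes (sinus
    rhythm, elevated paroxysmal-AF risk, AF present) with an explicit,
    configurable decision matrix and a 30-second minimum-duration AF
    detector.  Includes the postoperative-AF case/control evaluation
    protocol (24-hour pre-onset case windows, day-2 control windows,
    two-of-three positive patient calls), diagnostic-accuracy statistics
    from 2x2 contingency tables, and a seeded synthetic Holter cohort
    generator with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
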