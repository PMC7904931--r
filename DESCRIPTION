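Package: memfluor
Title: Fluorescence Spectroscopy Readouts of Membrane Dipole Potential,
    Order and Polarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for three classic fluorescence readouts of
    lipid-membrane physical state in liposome (LUV) experiments:
    di-8-ANEPPS 420/520 nm excitation ratiometry converted to membrane
    dipole-potential changes through a linear calibration with full error
    propagation; DPH-PC steady-state fluorescence anisotropy with
    G-factor correction; and time-correlated single-photon-counting
    (TCSPC) fluorescence decays fitted by iterative reconvolution with
    multi-exponential models and summarised as intensity-weighted mean
    lifetimes. Includes readers and writers for plain-text spectrum,
    polarized-intensity, decay and manifest files, a forward simulator of
    the full three-arm study design with known ground truth for
    parameter-recovery testing, and ANOVA/Tukey condition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
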