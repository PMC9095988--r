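Package: mueller3
Title: 3x3 Mueller Matrix Polarimetry for Backscattering Tissue Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linear (3x3) Mueller matrix polarimetric imaging of
    bulk tissue in backscattering mode. Reconstructs per-pixel Mueller
    matrices from rotating-polarizer intensity frames, derives polar
    decomposition (MMPD) parameters (diattenuation D, depolarization
    Delta, depolarization power 1-Delta, retardance delta) and the Mueller
    matrix transformation (MMT) anisotropy parameter t, computes frequency
    distribution histograms (FDH) with central moment coefficients P1-P4,
    and compares tissue regions across a sample cohort with t-tests. A
    synthetic two-region phantom generator emulates glioblastoma versus
    white-matter imaging studies so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
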