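Package: irpreproc
Title: Preprocessing Method Benchmarking for FT-IR Cell Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking preprocessing pipelines for Fourier
    transform infrared (FT-IR) absorbance spectra of single cells. Implements
    three denoising methods (Whittaker/Eilers smoothing, Savitzky-Golay,
    Fourier low-pass), six baseline corrections (Savitzky-Golay second
    derivative, rubber band, anchored polynomial, asymmetric least squares,
    and two iterative Mie-scattering extended multiplicative signal
    corrections), and three normalizations (constant band, total sum,
    probabilistic quotient), together with Kennard-Stone calibration/test
    splitting, NIPALS partial least squares regression and discriminant
    analysis with leave-one-out cross-validated latent-variable selection,
    and a grid runner that evaluates every denoise x baseline x normalize
    combination on both tasks. A synthetic generator produces class-structured
    cell-like spectra with baseline drift, Mie-type fringes, atmospheric
    artifact bands and scan-count-dependent noise, so the full pipeline is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
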