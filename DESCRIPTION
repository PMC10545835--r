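Package: kiwitrts
Title: Time-Resolved Transmittance Spectroscopy Analysis of Fruit Softening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved transmittance spectroscopy
    (TRTS) of soft fruit during postharvest storage. Implements the
    closed-form time-domain diffusion-approximation transmittance of a
    homogeneous slab with extrapolated-boundary dipole image sources,
    instrument-response-function convolution, bounded nonlinear
    least-squares estimation of the absorption and reduced scattering
    coefficients from photon-count histograms, Savitzky-Golay preprocessing
    and day-0 difference spectra, per-sample storage-time correlation
    tables for optical and color parameters, and PCA plus cross-validated
    SVM staging of softening. A synthetic-study generator renders complete
    two-condition storage experiments with Poisson counting noise so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
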