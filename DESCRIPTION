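Package: lensqpi
Title: Lensless Incoherent Quantitative Phase Imaging by Iterative Phase
    Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for lensless quantitative
    phase imaging (QPI) with a pinhole source, a transparent phase sample and
    a bare image sensor.  Implements a scalar-diffraction forward model
    (spherical and Fresnel quadratic propagation kernels, FFT-based
    convolution on a zero-padded computational grid), an iterative
    Gerchberg-Saxton phase retrieval algorithm with amplitude constraints at
    the sensor and sample planes, multi-distance refocusing for
    three-dimensional phase reconstruction, phase-only-filter correlation
    metrics, two-pass 2D phase unwrapping, phase/thickness conversion, and
    procedurally generated phase phantoms (binary masks, modulo-2pi ramps,
    Fourier-synthesized scattering layers, two-plane thick objects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    graphics,
    png,
    signal,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
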