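Package: RamanQuant
Title: Quantitative Regression Modelling of Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end chemometric regression for Raman spectroscopy:
    loading of two-column text spectra and matrix containers, a
    preprocessing chain (cropping, interpolation, median despiking,
    polynomial or EMSC baseline correction, Savitzky-Golay smoothing,
    area normalization), standard-deviation-shift data augmentation,
    four regression model families (NIPALS partial least squares,
    epsilon-support-vector regression with linear and Gaussian kernels,
    a one-hidden-layer tansig/purelin perceptron, and a one-dimensional
    convolutional network), six-statistic evaluation reports, portable
    JSON model archives, and a synthetic nailfold-glucose spectrum
    generator with exposed ground truth so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    e1071,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
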