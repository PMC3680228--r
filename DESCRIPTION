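Package: wmdemg
Title: Wavelet Maxima Density Analysis of Single-Channel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies individual finger flexions from a single channel of
    surface electromyography using the wavelet maxima density (WMD) technique.
    Provides a synthetic motor-unit action-potential (MUAP) train generator
    with volume-conduction amplitude structure, adaptive spectral-subtraction
    denoising against a per-subject background-noise template, detection of
    cross-scale-persistent modulus maxima of an undecimated biorthogonal
    (bior3.3) wavelet decomposition, windowed clustering of maxima magnitudes
    into centroid/density feature vectors, a linear twin support vector
    machine classifier, and a random-subsampling / cross-validation
    evaluation harness with per-class accuracy, sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
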