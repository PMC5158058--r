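Package: calentropy
Title: Markovian Entropy and Companion Measures for Calcium Activity Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the predictability of single-cell calcium
    fluorescence time series by representing each trace as a k-th order
    n-state Markov process over quantile-binned activity levels and scoring
    the normalized Shannon entropy of its transition matrix. Ships the
    companion measures commonly used alongside it (amplitude-ratio spike
    counting, average signal power, rescaled-range Hurst exponent),
    asymmetric-least-squares baseline correction for trend removal,
    population comparison statistics (two-sample Kolmogorov-Smirnov test,
    Cohen's d with effect-size star bands, sample-size subsampling and
    state/order parameter sweeps), a synthetic trace generator with known
    ground truth, and a command-line interface over CSV trace tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
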