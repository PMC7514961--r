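Package: twinpcg
Title: Heart Sound Classification with Wavelet-Fractal Features and a Twin Support Vector Machine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying phonocardiogram (heart sound) recordings as
    normal or abnormal. Each record is summarised by an 18-dimensional feature
    vector: the two-norms of the 16 terminal-node coefficient sequences of a
    four-level db6 wavelet-packet decomposition, the Shannon entropy of the
    wavelet-packet energy distribution, and a box-counting fractal dimension of
    the waveform. Classification uses a kernel twin support vector machine
    (two nonparallel hyperplanes fitted by a pair of small quadratic programs),
    with confusion-matrix metrics and stratified cross-validation. Includes a
    mono PCM WAV reader, a synthetic phonocardiogram generator for
    self-contained experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
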