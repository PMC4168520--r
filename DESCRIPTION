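Package: neuromkl
Title: Multiple Kernel Learning SVM for EEG Mental-Task and
    Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classification of multichannel EEG with a multiple kernel
    learning support vector machine (SimpleMKL: reduced-gradient descent
    on simplex-constrained kernel weights with duality-gap termination),
    fed either by wavelet-packet entropy features of the classical EEG
    rhythms (delta/theta/alpha/beta) or by spectral Granger-causality
    connectivity features between averaged brain regions.  Includes an
    ICA + orthogonalized empirical-mode-decomposition preprocessing
    stage, deterministic synthetic-EEG generators (band-power profiles
    and coupled vector-autoregressions with known directed coupling),
    one-versus-rest multiclass extension, and a stratified/subject-wise
    cross-validation harness with CSV + JSON I/O.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
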