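Package: protoneuro
Title: Electrochemical and Information-Theoretic Analysis of Proteinoid Protocell Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the electrical behaviour of proteinoid
    (thermal protein) protocells and their neurotransmitter-modified variants.
    Provides cyclic-voltammetry feature extraction (redox peak statistics,
    integrated charge, charge-decay fitting, zero crossings, hysteresis area),
    spontaneous spike-train detection and amplitude/period statistics,
    electrochemical impedance spectroscopy with R(RC)(RC) equivalent-circuit
    fitting, distribution comparison (two-sample Kolmogorov-Smirnov, Cohen's d),
    and information-theoretic complexity metrics (Lempel-Ziv-Welch complexity,
    a perturbational complexity index, window integration score, and an
    entropy-minus-mutual-information integrated-information statistic).
    A synthetic-signal module generates spiking voltage traces, multi-cycle
    voltammograms and impedance spectra with the statistical structure the
    analyses assume, so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
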