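Package: qamsr
Title: Single-Marker (QAMS) Quantification of Nucleosides from Targeted LC-MS Peak Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multiple components using a
    single marker (QAMS) in targeted LC-MS/MS assays, built around a
    nine-nucleoside panel with guanosine as the internal reference.
    Implements external-standard linear calibration with LOD/LOQ
    estimation, relative correction factors and their cross-column
    robustness summaries, single-marker back-calculation of
    concentrations, method-validation statistics (precision,
    repeatability, spike recovery, one-way ANOVA), vector-angle-cosine
    agreement between quantification methods, and a synthetic peak-area
    simulator (dilution ladders, per-column sensitivity drift,
    multiplicative noise, below-LOQ censoring) so the whole workflow can
    be exercised without instrument data. A command-line interface ties
    the stages into reproducible runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
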