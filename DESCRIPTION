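Package: p2ensemble
Title: Ensemble P2 Receptor Modeling of ATP-Evoked Calcium Responses
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize purinergic (P2X/P2Y) receptors by Hill
    dose-response fitting, extract amplitude, duration (width at half
    maximum) and area-under-curve features from single-cell fluo-4
    calcium fluorescence time series, and decompose ensemble ATP
    dose-response curves into signed linear combinations of per-receptor
    Hill basis functions, revealing inhibitory (heterologous
    desensitization-like) contributions. Includes an embedded catalog of
    published per-receptor Hill parameters, a seeded synthetic-data
    generator emulating multi-experiment single-cell calcium imaging,
    landmark (two-peak) analysis of amplitude dose dependence, and
    command-line entry points for the end-to-end analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
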