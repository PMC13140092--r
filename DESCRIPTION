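Package: postureP3
Title: Simulation and Analysis of P3 Oddball ERPs Under Postural Dual-Task Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying whether quiet standing diverts attentional
    resources from a concurrent auditory oddball task. Provides a synthetic
    mobile-EEG generator (oddball stimulus sequences, ERP templates, pink
    noise, artifact bursts, EDF output), ERP preprocessing (zero-phase
    band-pass filtering, epoching, baseline correction, amplitude-threshold
    artifact rejection), univariate P3 measures (mean amplitude, fractional
    area latency, paired condition tests), time-resolved multivariate
    decoding of standing versus sitting with averaged pseudo-trials and a
    per-timepoint linear support vector machine, cluster-mass permutation
    inference on decoding accuracy, and ERP data-quality estimation via the
    analytic and bootstrapped standardized measurement error.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
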