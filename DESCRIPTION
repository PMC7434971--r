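Package: dreamdyn
Title: Phase-Transition Analysis of Ordered Short-Document Series
Version: 0.1.0
Authors@R:
    person("Process", "Research", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps an ordered corpus of short documents (e.g., dream
    narratives collected across a psychotherapy) into a correspondence
    analysis factor space, quantifies each document's affective charge as
    the Euclidean norm of its squared-cosine vector, and searches the
    resulting series for a phase-transition-like change point using
    dynamic complexity, unthresholded recurrence plots, Stockwell
    time-frequency analysis, and variance-cost change-point detection.
    Includes trend models (binary logistic regression on time, ARIMA with
    ACF/PACF identification and Ljung-Box diagnostics) and a synthetic
    corpus generator with a ground-truth regime shift so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
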