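Package: eegtraffic
Title: Inter-Departure Time Analysis of EEG Scalogram Troughs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats multichannel EEG as a trace of departing units of
    information, in the spirit of teletraffic engineering. Epoched
    recordings are resolved in time and frequency with a complex Morlet
    continuous wavelet transform; troughs of scalogram power, filtered by a
    topographic-prominence threshold, are marked as message departures; the
    positive intervals between successive departures are fitted with
    two-parameter Gamma (and other candidate) distributions by maximum
    likelihood and ranked by chi-square goodness of fit. The fitted shape
    and scale parameters are interpreted through an Erlang serial-server
    queueing model (closed forms, Laplace transforms and a stochastic
    simulator) and compared across paired experimental conditions with
    mean-centered task partial least squares, including permutation tests
    and bootstrap salience ratios. A synthetic-EEG generator with known
    ground truth (1/f background plus burst-gated oscillations) makes the
    whole pipeline testable without any recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
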