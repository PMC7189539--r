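Package: seatcomp
Title: Detecting Compensatory Trunk and Shoulder Motions from Seat Pressure Distributions
Version: 0.1.0
Authors@R: person("seatcomp", "maintainers", email = "maintainers@seatcomp.org", role = c("aut", "cre"))
Description: Tools for recognising compensatory trunk and shoulder motions
    (trunk rotation, trunk lean-forward, shoulder elevation) during seated
    reaching from body-pressure-mattress recordings. Provides a plain-text
    reader/writer for 32x32 pressure-frame streams, a synthetic seated-pressure
    simulator with per-subject variability, extraction of ten centre-of-pressure
    and load-distribution features, a radial-basis-function support vector
    machine with leave-one-subject-out cross-validation and F1 metrics, and an
    online sliding-window detector that emits debounced compensation events for
    feedback systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
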