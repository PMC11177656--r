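Package: pbrtqc
Title: Patient-Based Real-Time Quality Control with EWMA Control Charts
Version: 0.1.0
Authors@R:
    person("pbrtqc", "authors", email = "lab@example.org",
           role = c("aut", "cre"))
Description: Build, run and evaluate patient-based real-time quality control
    (PBRTQC) models for clinical laboratory analytes. Exponentially weighted
    moving average (EWMA) control charts are run over truncated patient-result
    streams; truncation ranges are estimated either by Box-Cox normalisation
    (the traditional approach) or by a biological-variation heuristic. Alarms
    are raised from control limits and Westgard multirules, scored against a
    quality-risk event register (error detection probability, false positive
    rate, average number of patients to error detection, ROC/AUC), and
    candidate models are compared with an optimality filter. A stream
    simulator injects step bias, drift and imprecision inflation to provide
    ground truth for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
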