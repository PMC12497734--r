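Package: clustMEA
Title: Spike-Train Analysis of Clustered Cortical Networks on Multi-Electrode Arrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-electrode array (MEA) recordings from
    four-cluster cortical cultures: precision-time spike detection from raw
    voltage, string-method burst and network-burst detection, spiking/bursting
    activity metrics, instantaneous-firing-rate based cluster activation
    sequences with run-length statistics, Shannon diversity/equitability and a
    permutation Monte Carlo null, Total Spiking Probability Edges (TSPE)
    functional connectivity with spatial and physiological edge filtering,
    coincidence-index synchrony, Hill-equation dose-response fitting, and the
    paired statistical comparisons used for condition-versus-baseline studies.
    Includes a seeded synthetic-data generator with planted ground truth
    (activation motifs, persistence, directed connectivity) so that every
    analysis stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
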