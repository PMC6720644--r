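Package: wlfuse
Title: Multi-Sensor Workload Fusion with a Mamdani Fuzzy Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fuses flight-performance and physiological features (ECG,
    respiration, eye tracking) into a single operator-workload score on the
    NASA-TLX scale. The pipeline z-score standardizes per-phase feature
    tables, reduces dimension by correlation-matrix principal component
    analysis with contribution-rate component selection, and feeds the
    retained components into a Mamdani-type fuzzy neural network: composite
    Z-shaped/Gaussian/S-shaped fuzzification, minimum-rule applicability,
    applicability normalization, and weighted defuzzification. Output
    weights are learned by error-feedforward batch gradient descent with an
    error-tolerance stopping rule. A seeded synthetic flight-campaign
    generator and a command-line workflow (simulate, fit, predict, report)
    make every stage testable without access to cockpit recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
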