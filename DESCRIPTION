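Package: mfcbod5
Title: Rapid BOD5 Estimation from Microbial Fuel Cell Voltage Traces
Version: 0.1.0
Authors@R: person("MFC", "Analytics", email = "mfc@example.org", role = c("aut", "cre"))
Description: Tools to estimate 5-day biochemical oxygen demand (BOD5) from
    truncated microbial-fuel-cell (MFC) voltage discharge curves sampled on a
    5-minute grid. Supports a direct route (multilayer perceptron regression
    from a 2-24 h voltage window to one BOD5 value) and an indirect route
    (curve completion by a multilayer perceptron, coulombic charge integration
    via Ohm's law, and a linear charge-to-BOD5 calibration), together with a
    synthetic discharge-curve generator, block k-fold cross-validation,
    evaluation metrics, and CSV input/output for the 1511-sample canonical
    voltage frame.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
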