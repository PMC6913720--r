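Package: gaitpower
Title: Energy Expenditure During Gradient Walking from Insole Step Frequency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the metabolic power of walking on inclined surfaces from
    body mass, walking speed, surface gradient, and step frequency measured by
    pressure-sensing shoe insoles. Implements a piecewise mechanistic model
    (linear in kinetic and potential power uphill, with an additional quadratic
    potential term downhill), a dual-threshold hysteresis state machine that
    extracts foot-contact events and cadence from 10 Hz insole pressure traces,
    processing of cumulative indirect-calorimetry records into net above-basal
    expenditure rates, the two-stage least-squares calibration of the model
    coefficients, evaluation metrics (RMSD, percent error), and a synthetic-data
    generator that emulates the full measurement chain for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    yaml,
    data.table
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
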