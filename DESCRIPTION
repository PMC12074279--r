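Package: eiscap
Title: Virtual Instrument for Capacitive Field-Effect (EISCAP) Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates an Al/p-Si/SiO2/Ta2O5 electrolyte-insulator-
    semiconductor capacitor (EISCAP) pH and penicillin biosensor and the
    three measurement modes of a portable impedance-analyzer readout
    station: electrochemical impedance spectra, high-frequency
    capacitance-voltage sweeps with automatic working-point selection, and
    constant-capacitance (ConCap) readout driven by a PID feedback loop.
    Includes calibration analysis (curve-shift extraction, least-squares
    sensitivity fits with standard errors, multi-sensor aggregation),
    CSV import/export with self-describing metadata headers, YAML/JSON
    device configuration, and a command-line interface. The simulator sits
    behind a small device contract so a real instrument backend can be
    substituted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
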