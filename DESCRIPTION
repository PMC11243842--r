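Package: fuzzphys
Title: Fuzzy-Logic Stress Assessment from Wearable Physiological Parameters
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses psychological stress in three classes (Calm, Normal,
    Stressed) from eight wearable-derived physiological parameters (heart
    rate, pulse-rate variability, respiratory rate, SpO2, galvanic skin
    response, body temperature, systolic and diastolic blood pressure) using
    a fuzzy inference system: trapezoidal/triangular membership functions
    over clinical reference ranges, a three-rule base, and weighted-average
    defuzzification onto a 1-3 scale. Also provides crisp clinical banding
    of single parameters, blood glucose (fasting and postprandial) and blood
    pressure; synthesis of two-channel photoplethysmography waveforms and
    estimation of heart rate, RMSSD pulse-rate variability, respiratory rate
    and SpO2 from them; a synthetic diabetic-cohort simulator with a
    four-phase, five-day meal/medication protocol and stress-glucose-blood
    pressure coupling; multi-class confusion-matrix metrics; and CSV/JSONL
    record input/output with a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml, pracma
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
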