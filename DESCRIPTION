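Package: hiveESF
Title: Detection and Decoding of Honeybee Social Signals from Hive
    Electrostatic-Field Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for long-term monitoring of honeybee colonies through
    electrostatic-field (ESF) recordings taken inside the hive. Provides a
    binary container and CSV/WAV conversion for six-channel 24-bit ESF
    streams, entrance-capacitance activity traces and hive telemetry; a
    parametric simulator of the three stereotyped colony signals (waggle
    runs, short pulses, fanning) with ground-truth annotations; STFT
    band-power spectral primitives; a rule-based detector that segments,
    classifies and scores these signals, counts waggle cycles and decodes
    foraging distance; entrance-traffic analytics; and environment
    correlation and run-summary reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
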