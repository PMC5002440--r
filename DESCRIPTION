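Package: pairedval
Title: Validation of Dense Extracellular Probes with Paired Juxtacellular Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for ground-truth validation of dense silicon polytrode
    recordings against simultaneous juxtacellular (cell-attached) recordings.
    Provides dual-manipulator coordinate co-registration (tilt transform plus
    least-squares affine software correction), probe geometry factories and raw
    binary I/O, zero-phase Butterworth band-pass filtering, juxtacellular spike
    detection and juxtacellular-triggered averaging (JTA) with peak-to-peak
    footprint mapping, dual-threshold flood-fill spike detection with
    peri-event-time-histogram evaluation, closed-form electrode sensitivity
    volume estimates, and a seeded synthetic paired-recording generator with
    known ground truth so every analysis stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
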