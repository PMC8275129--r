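Package: sleepephys
Title: Sleep-State Classification and Synaptic Stability Analytics for
    Rodent Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying synaptic stability across natural sleep and
    wake in chronically recorded rodents. Implements real-time sleep/wake
    scoring from EEG band-power ratios, EMG deflections and video movement
    (an adaptive-threshold decision tree in 10-s epochs) plus a post hoc
    random-forest scorer; hypnogram analytics including sleep/wake-dense
    epoch detection and NREM delta-power homeostasis; template-matching
    miniature EPSC detection with the standard inclusion filters; evoked
    field potential amplitude, slope and current-source-density measurement
    with behavioral-state normalization and sandwich change statistics; and
    bootstrap-gated stimulus-evoked spiking analysis. A seeded synthetic-data
    generator produces ground-truthed polysomnography, voltage-clamp and
    laminar field recordings so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
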