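Package: scalodetect
Title: CNN Detection of Seizures and Spike-Wave Discharges in Chronic Rodent EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and automated detection pipeline for chronic
    single-channel rodent EEG. Generates seeded synthetic cohorts of
    post-implant recordings containing convulsive seizures (onset spiking,
    optional mid-ictal depression, post-ictal depression, inter-ictal bursts)
    and 7-12 Hz spike-wave discharges with exact ground-truth annotations;
    segments records into 10 s epochs; converts epochs to Morlet continuous
    wavelet transform scalogram images; classifies them with a small
    convolutional neural network at a fixed confidence threshold; aggregates
    detections into per-interval duration timelines keyed to post-implant
    latency; and runs cross-over training experiments and group statistics
    (two-sample t tests, two-way ANOVA) on replicate cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    png,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
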