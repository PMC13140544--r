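Package: stnprop
Title: Spatiotemporal Analysis of Movement-Related Subthalamic LFP Synchronization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for movement-related local field potentials
    recorded from multi-contact deep brain stimulation leads in the
    subthalamic nucleus (STN). Provides baseline-normalized multitaper
    synchronization estimates in beta and 60-400 Hz sub-bands,
    power-weighted kernel-density hotspot localization in MNI-like
    coordinates, hotspot propagation and volatility statistics with
    surrogate (random-contact) inference, and clinico-electrophysiological
    feature ranking via stagewise least-squares boosting with
    leave-one-out cross-validation. A synthetic-cohort generator with
    planted spectral-spatial ground truth supports end-to-end validation
    and calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    jsonlite,
    yaml,
    data.table,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
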