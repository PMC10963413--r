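Package: workloadr
Title: Multimodal Mental-Workload Assessment from Brain, Heart, and Eye Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multimodal mental-workload
    studies. Generates synthetic multi-session recordings for six biomedical
    modalities (fNIRS, EEG, ECG, PPG, EOG, eye-tracking) with known injected
    session (learning) and condition (workload) effects; processes each
    modality with the field-standard chain (modified Beer-Lambert law
    haemodynamics, Welch band powers and engagement indices, heart-rate
    variability in time and frequency domains, saccade and fixation
    detection); and runs the block-level statistical layer: per-measure linear
    mixed models with REML, Benjamini-Hochberg false-discovery-rate control
    across channels, partial eta-squared effect sizes, and a repeated PCA
    variance partition across modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    signal,
    nlme,
    lmerTest,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
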