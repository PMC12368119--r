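Package: pupilevents
Title: Detecting Cognitive Events from Task-Evoked Pupillary Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting cognitive events
    (stimulus onsets) from task-evoked pupillary responses. Generates
    multi-participant 250 Hz pupil-diameter and gaze recordings across four
    cognitive tasks plus rest, builds standardized labeled 1-s windows around
    stimulus onsets, rebalances training data with SMOTE, trains four neural
    network architectures (CNN, BiLSTM, RNN, MLP) with a composite
    classification-plus-reconstruction loss, evaluates with Matthews
    correlation and companion metrics, computes permutation feature
    importance, and replays recordings as causal streams with rolling-baseline
    normalization for online event detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
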