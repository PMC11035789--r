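Package: ssleeg
Title: Self-Supervised Representation Learning for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for self-supervised representation learning on multichannel
    EEG-like time series, aimed at emotion recognition with few labels.
    Implements differential-entropy band features over 1-s windows, three
    pretext tasks that manufacture pseudo-labels from unlabeled signal
    structure (Relative Position, Temporal Shuffling, and Contrastive
    Predictive Coding with the InfoNCE objective), a small trainable encoder
    and causal context model, and a downstream evaluation harness with
    trial-grouped 10-fold cross-validation, accuracy and macro-F1 metrics,
    valence/arousal label construction, and Wilcoxon pairwise method
    comparison. A bundled synthetic-EEG generator with known class-dependent
    band-power structure makes the whole pipeline testable end to end without
    any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
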