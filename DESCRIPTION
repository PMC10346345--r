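Package: neurogait
Title: EEG-Based Classification of Stable and Unstable Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discriminating stable from unstable
    treadmill walking using scalp EEG synchronized to the gait cycle. Covers
    synthetic session generation (64-channel EEG with gait-phase-locked
    alpha/beta/theta oscillations, heel-marker and ground-reaction-force
    waveforms, injectable blink/line-noise/EMG artifacts), BrainVision and
    delimited-file input/output, zero-phase band-pass and band-stop filtering,
    FastICA decomposition with rule-based component scoring and artifact
    removal, heel-strike detection from marker minima and force onsets,
    gait-cycle segmentation with 0-100% time normalization, a 29-per-channel
    biomarker set (time-domain statistics, Hjorth parameters on alpha and beta
    band signals, entropy measures, Daubechies-2 wavelet detail energies),
    Wilcoxon-statistic feature ranking with correlation-constrained greedy
    selection, five classifiers (RBF support vector machine, random forest,
    gradient-boosted trees, stacked LSTM, ChronoNet) and stratified
    cross-validated evaluation with accuracy, macro precision/recall/F-score,
    Matthews correlation and one-vs-rest ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    e1071,
    ranger,
    xgboost,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
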