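---
title: "Gait-cycle-synchronized EEG classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-cycle-synchronized EEG classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogait)
```

## The problem

Walking instability has a cortical signature: balance-demanding walking is
accompanied by suppressed beta-band (12--30 Hz) power over sensorimotor
cortex and elevated theta-band (4--7 Hz) power over frontal-midline areas.
`neurogait` implements a complete analysis chain that asks whether such
signatures, extracted from scalp EEG *synchronized to the gait cycle*, are
sufficient to discriminate stable from unstable treadmill walking: normal
walking (NW) and walking with center-of-mass visual feedback (COM) as the
stable conditions, walking under a Stroop dual task (STROOP) and under
medio-lateral platform perturbations (MLP) as the unstable ones.

The analysis unit is the gait cycle — right heel strike to the next right
heel strike. Each cycle yields one EEG segment, one feature vector, and one
classification instance.

## The synthetic-data generator

Real recordings of this kind are not freely redistributable, so the package
ships a generator (`session_config()`, `generate_session()`) whose output
has the statistical structure every downstream stage assumes, with known
ground truth. It is first-class, tested code, not a fixture.

Each trial is synthesized as:

* **EEG background**: spectrally shaped white noise with a 1/f power slope
  (flat below 1 Hz), 6 µV SD per channel — the standard broadband EEG
  surrogate.
* **Band-limited sources**: zero-phase-filtered white noise confined to the
  alpha (8--12 Hz), beta (12--30 Hz) and theta (4--7 Hz) bands, projected
  onto posterior, sensorimotor and frontal-midline channel groups of a
  64-channel 10--20 montage with source SDs of 18, 14 and 12 µV at the core
  channels. Every source is amplitude-modulated at stride frequency with
  depth 0.2, so the signal carries genuine cycle-locked structure that
  segmentation must preserve.
* **Condition effects**: multiplicative band-*power* factors (amplitude is
  scaled by their square root). Defaults: NW and COM are identical (all
  factors 1); STROOP applies beta ×0.75 and theta ×1.35; MLP applies beta
  ×0.70 and theta ×1.25. The asymmetry encodes the physiological
  expectation that a cognitive dual task loads frontal-midline theta
  hardest while a mechanical perturbation loads sensorimotor beta hardest;
  it also makes the two unstable conditions partially separable, as they
  must be for four-way classification to beat the 50% ceiling that exactly
  identical unstable conditions would impose. These effect sizes are
  deliberately moderate: classification should be clearly above chance but
  not trivial.
* **Gait**: stride intervals are Gaussian with mean 1.10 s and a
  coefficient of variation of 3% (stable) or 7% (unstable), truncated at
  ±3 SD. Heel height is a raised-cosine swing bump whose minimum falls
  exactly at each heel strike (sub-millimeter marker noise, 0.1 mm SD, as
  typical for optical capture); the vertical ground reaction force is a
  double-peaked stance curve over the first 62% of the cycle, exactly zero
  in late swing, rising at ≈4000 N/s at contact.
* **Artifacts** (`inject_artifacts()`): Poisson-timed 300 ms raised-cosine
  blinks with a frontal-dominant topography (0.2/s, 120 µV), common-phase
  60 Hz line noise (5 µV), and Poisson-timed broadband (30--100 Hz) EMG
  bursts on temporal channels. Ground-truth time stamps are kept in the
  recording's `artifact_log`.

What the generator does *not* emulate: volume-conducted source mixing from
a head model, non-stationary drifts, electrode impedance changes, movement
artifacts phase-locked to steps, or any genuine neural dynamics beyond
band-limited power. A passing end-to-end test therefore demonstrates that
the pipeline recovers planted spectral condition differences through
segmentation, cleaning, feature extraction and classification — not that
real gait instability is classifiable at any particular accuracy.

## Preprocessing

`bandpass_bandstop()` applies 4th-order Butterworth stages — high-pass
1 Hz, low-pass 70 Hz, band-stop 55--65 Hz — each forward-backward
(zero-phase), so gait-event timing is never shifted. About one second of
reflection padding keeps the start-up transients of the narrow notch and
the low high-pass cutoff out of the data. The stages are applied as
separate sections because a single transfer-function realisation of the
composite 1--70 Hz + notch design is numerically ill-conditioned at a
1000 Hz rate.

`decompose_ica()` is FastICA with the logcosh contrast in symmetric mode
(deflation as a fallback), on PCA-whitened data, deterministic under a
seed. The unmixing matrix is estimated on at most `max_samples` evenly
spaced samples for speed; sources are then computed from all samples and
scaled to exactly unit variance. When fewer components than channels are
requested, the part of the signal outside the component subspace is
retained and added back after artifact removal, so reduced-rank cleaning
never distorts what it did not model. The pipeline default is 32 components
estimated on 10,000 samples; `decompose_ica()`'s own default is full rank,
for which reconstruction is exact to machine precision.

`score_components()` replaces a trained component classifier with
interpretable evidence rules mapped through a softmax: low-frequency
(<4 Hz) power fraction weighted by frontal topography (eye), 55--65 Hz
power concentration (line noise), >30 Hz power fraction times spectral
flatness (muscle), single-channel loading dominance (channel noise), brain
as the residual evidence. `remove_artifacts()` zeroes every component whose
strongest non-brain probability exceeds the classical 0.90 threshold and
back-projects the rest; channel count and length are always preserved. The
rules are not a general artifact classifier — they are calibrated for the
stereotyped artifact families the generator plants, and the tests verify
exactly that contract (blink windows cleaned, posterior alpha untouched).

No re-referencing is applied before ICA; the montage is used as recorded.

## Gait events and segmentation

Heel strikes come from two independent sensors. `detect_events_marker()`
low-passes the heel height at 6 Hz, picks local minima with prominence at
least 30% of the signal range and 0.4 s minimum separation, and refines
each minimum by parabolic interpolation to sub-sample precision — the
lowest heel position during walking is the heel strike.
`detect_events_grf()` finds upward threshold crossings (20 N default)
preceded by at least 50 ms of unloaded swing, with linear-interpolated
crossing times. `reconcile_events()` keeps marker events confirmed by a
force event within 50 ms; marker timing is primary because the forceplate
onset systematically lags initial contact by a few milliseconds.

`segment_and_normalize()` cuts the cleaned EEG into half-open cycles
`[e_k, e_{k+1})` — no sample belongs to two cycles — discards cycles
outside 0.4--2.5 s (logged), keeps the untouched native-rate slice, and
linearly interpolates each channel onto 100 equally spaced points of the
0--100% gait cycle. Linear interpolation is monotone and cannot overshoot
the raw amplitude range; cycles are right-heel-strike based by default
because the perturbation protocol being emulated triggers at right heel
strike.

## The 29-per-channel feature set

Per channel and cycle:

* **9 time-domain features** on the 100-sample normalized signal: mean
  absolute deviation, RMS, maximum, minimum, mean, variance, skewness,
  kurtosis, and average amplitude change
  `AAC = Σ|x[i+1]−x[i]|/(n−1)`. All moments use the population divisor
  `n`, for consistency with the variance-based Hjorth activity.
* **6 Hjorth parameters**: activity (variance), mobility
  (`sqrt(var(Δx)/var(x))`) and complexity (mobility of the derivative over
  mobility of the signal), computed on the *native-rate* cycle slice
  band-filtered to alpha and beta with 4th-order zero-phase Butterworth
  filters. Derivatives are unscaled first differences. A pure sinusoid has
  complexity 1, which the tests assert to 1%.
* **5 entropies** on the normalized signal: Shannon entropy of a 16-bin
  amplitude histogram (natural log, `0·log 0 := 0`; a constant signal has
  entropy 0, a uniform 16-bin fill has `ln 16`), log-energy
  `Σ log x_i²` (zero samples contribute 0), threshold entropy
  `#{|x_i| > ε}`, SURE entropy `n − #{|x_i| ≤ ε} + Σ min(x_i², ε²)`, and
  norm entropy `Σ|x_i|^p`, with `ε = 0.2·SD(x)` and `p = 1.5` by default,
  both configurable. The entropies are computed on the raw amplitude
  samples (not on wavelet coefficients), a documented, configurable choice.
* **9 wavelet features**: detail energies `E(d1)…E(d8)` of a Daubechies-2
  decomposition of the native-rate slice, plus the population SD of the
  eight detail energies.

The decomposition depth deserves a note. The source protocol names a
four-level decomposition yet lists detail energies 1--8; those are
irreconcilable, so the depth is a parameter with default 8 — the choice
under which all listed features exist. Eight levels are infeasible on 100
samples (`floor(log2(n/3)) ≥ L` is required), which is why wavelet features
use the ~1100-sample native-rate slice. The transform is *periodized*
(circular) rather than symmetric-padded: the periodized orthonormal filter
bank partitions signal energy exactly (Parseval to machine precision,
asserted at 1e-6), whereas symmetric padding inflates coefficient energy
and has no exact energy decomposition — for energy features, exactness
wins. Odd lengths are zero-padded to even per level, which leaves energy
unchanged.

A 64-channel cycle therefore yields `64 × 29 = 1856` features, named
`<channel>__<feature>`, in stable order (`build_feature_vector()`,
`build_feature_table()`). Degenerate inputs (zero variance) produce flagged
zeros with warnings rather than NaNs; any other non-finite value is an
error.

## Feature selection

`wilcoxon_z()` is the standardized Mann–Whitney u-statistic with the exact
tie correction,
`U = #{x_i > y_j} + ½·#{ties}`,
`z = (U − n₁n₂/2)/σ_U`. Features are ranked by `|z|`
(`rank_features()`); with more than two classes the score is the maximum
`|z|` over one-vs-rest splits, which keeps the stated two-sample statistic
and favors any-class discriminability. Ties in score are broken by column
order, so the ranking is deterministic.

`select_features()` then greedily accepts the highest-ranked feature whose
*mean* absolute Pearson correlation with the already selected set is at
most the threshold (0.8 default), up to `k = 40` features.
"Cross-correlation coefficient" is read as zero-lag Pearson correlation
across cycles — the features are not time series. Selection runs once per
labeling by default (mirroring a pipeline in which selection precedes
classification); `per_fold = TRUE` re-selects inside every training fold
for a leakage-free protocol, since the emulated pipeline leaves this
ambiguous. Both modes are tested; at the synthetic effect sizes the two
give indistinguishable accuracies, but the once-per-run default should be
kept in mind when interpreting small margins on real data.

## Classifiers

Feature models consume the selected feature table; sequence models consume
the channels × 100 normalized-cycle tensor ("raw EEG in time-series
format"). That split is the natural reading of the emulated design and is
fixed in `train_model()`'s input contract.

* **SVM** (RBF kernel, `C = 1`, `γ = 1/(d·var)`), via `e1071`, on features
  standardized with training-fold statistics.
* **Random forest**: 500 trees, `√d` features per split, via `ranger`.
* **Gradient-boosted trees**: 300 rounds, depth 4, learning rate 0.1, via
  `xgboost`.
* **Stacked LSTM**: two LSTM layers of 64 units, dropout 0.3 after each,
  dense softmax head.
* **ChronoNet**: three inception-style blocks — parallel 1-D convolutions
  with exponentially increasing kernels (2, 4, 8), 32 filters each, stride
  2, concatenated to 96 channels — followed by four GRU layers of 32 units
  with dense feed-forward connectivity (layer inputs: conv output; GRU1;
  GRU1⊕GRU2; GRU1⊕GRU2⊕GRU3), dropout 0.2, linear softmax head. Temporal
  lengths fall 100 → 50 → 25 → 13 (ceiling mode). `build_chrononet()`
  returns the layout as a JSON-serializable description.

The two sequence models run on a small reverse-mode automatic
differentiation engine written for this package (R matrix operations plus
compiled im2col/col2im kernels), trained with Adam (learning rate 1e-3,
batch 64, gradient-norm clipping at 5), cross-entropy loss, optional
stratified validation split with early stopping (patience 10), and
per-epoch loss/accuracy history. Every gradient path is verified against
finite differences in the test suite. Training is single-threaded and
seeded, hence bit-reproducible. No published hyperparameters exist for the
emulated study; the values above are conventional defaults and all are
exposed in `model_spec()`.

## Evaluation

`make_labels()` implements the three labelings: four-class (NW, STROOP,
COM, MLP), three-class (MLP dropped), and two-class (NW+COM = stable,
STROOP+MLP = unstable). `crossvalidate()` uses stratified 5-fold splits at
cycle level by default; `groups =` (or `group_by_subject` in the pipeline
config) switches to subject-wise folds, because cycle-level folds let
cycles from the same subject appear in both train and test — with only a
handful of subjects, both protocols are worth inspecting.

The metric panel (`compute_metrics()`) is accuracy, macro-averaged
precision/recall/F-score, the Matthews correlation coefficient in its
multiclass covariance form (identical to the classical binary formula for
two classes, asserted to 1e-12), and macro one-vs-rest ROC AUC with
per-class ROC curves by score thresholding. A single AUC quantity is
computed and reported under both the "ROC area" and "AUC" names, because
the two columns of the emulated report tables cannot be reconciled into
distinct definitions. Metrics are computed on the pooled out-of-fold
predictions — every cycle is predicted exactly once, so reported accuracy
equals the confusion-matrix trace ratio identically; per-fold accuracies
are recorded alongside and coincide with the pooled value up to fold-size
rounding.

## Problem sizes and numerical choices

The package's own evaluation scale is 4 subjects × 4 conditions × 120 s
trials (~1700 cycles), chosen as the point where planted effects are
recoverable on a single CPU; the generator's per-type defaults
(13 subjects, 300 s) describe the emulated study itself. At the evaluation
scale, feature-based classifiers recover the stable/unstable contrast at
roughly 0.75 accuracy — close to the information-theoretic ceiling the
planted effect sizes admit (per-cycle band-power estimates carry 20--50%
sampling noise). The sequence models behave differently: ChronoNet fits
the training cycles perfectly but generalizes to only ~0.65--0.69 here, a
textbook small-data regime (~170k parameters against ~1400 training
cycles, with 51 of 64 channels carrying no class signal), and pilot sweeps
over dropout (0.2--0.6), decoupled weight decay, input-noise augmentation
and last-step vs mean-pooled GRU heads all land within a few points of
that plateau. Deep-model accuracy at this scale should therefore be read
as a lower bound that improves with corpus size, not as the architecture's
ceiling. The evaluation-scale training configuration is 10 epochs,
learning rate 1e-3, dropout 0.4 and input-noise augmentation 0.5 with no
validation split; accuracies plateau by roughly epoch 10. `demo_config()`
(2 subjects × 60 s, random forest) exercises the full path in about two
minutes.

Other numerical choices: sample indices are 0-based in time
(`t = start + s/fs`), cycle spans half-open; EEG and motion capture share
`t = 0` (the generator emulates hardware-synchronized acquisition, and the
segmentation assumes it); ICA convergence tolerance 1e-4 with at most 200
symmetric iterations; argmax label ties break to the lowest class index;
filter initial conditions solve the steady-state equations, falling back to
zero state for numerically singular narrow-band designs (the reflection
padding makes the difference negligible).

## Known limitations

* The component scorer is a rule-based stand-in tuned for stereotyped
  artifacts; it does not generalize to the full zoo of real EEG artifacts.
* Synthetic sources are spatially crude (region weight maps, no forward
  model), so topography-sensitive methods are only weakly exercised.
* Classification accuracies on synthetic data say nothing quantitative
  about real walking EEG; they validate the machinery, not the physiology.
* Cycle-level cross-validation shares subjects across folds; use
  subject-wise folds for generalization claims.
* The BrainVision writer emits only multiplexed IEEE float32 (the reader
  additionally accepts INT_16); EDF/BDF and C3D are out of scope.
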