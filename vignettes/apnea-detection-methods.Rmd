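---
title: "Detecting sleep apnea from single-lead ECG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea from single-lead ECG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneanet)
```

## The problem

Sleep apnea (SA) — repeated cessation or reduction of breathing during
sleep — leaves a characteristic fingerprint in the electrocardiogram:
apneic episodes drive a cyclic bradycardia–tachycardia oscillation of the
heart rate, visible as slow swings in the RR-interval series, together
with respiration-linked modulation of the R-wave amplitude. A single-lead
ECG, recordable by cheap wearable devices at home, therefore carries
enough information to screen for SA without full polysomnography.

`apneanet` classifies each one-minute segment of a recording as apneic or
normal and then diagnoses the whole recording through the apnea–hypopnea
index (AHI). The pipeline is:

1. **R-peak detection** on the raw signal;
2. **RR/amplitude extraction and artifact cleaning**;
3. **windowing**: each labeled minute, together with ±2 minutes of
   context, becomes a five-minute window resampled to two aligned
   900-point channels (RR in seconds, amplitude in mV);
4. **classification** by a stacked convolutional / bidirectional-GRU
   network with dot-product attention;
5. **per-recording diagnosis**: AHI = 60·N/T over the T evaluated
   minutes, with N predicted apneic; a recording is called SA when
   AHI > 5 (strictly).

## Preprocessing

**R-peak detection** (`detect_r_peaks()`) is a Hamilton-style detector:
zero-phase Butterworth band-pass at 8–16 Hz (the QRS energy band),
rectification, an 80 ms moving-average envelope, and adaptive
thresholding at 0.3125 of a running average of accepted envelope peak
heights with a 200 ms refractory period. Each detection is refined to the
local maximum of the *raw* signal within ±50 ms so the reported sample
sits on the R-wave apex, which is what the amplitude channel needs. An
absolute envelope floor of 0.02 mV prevents numerical ripple in silent
stretches from seeding the adaptive threshold. All of these are exposed
as arguments; the defaults are the published constants of this detector
family and are not tuned to any dataset.

**Artifact cleaning** (`clean_rr()`) operationalises "physiologically
unexplained" RR values as: outside [0.4, 2.0] s (30–150 bpm) or deviating
by more than 20 % from a 5-point running median. Flagged RR values are
replaced by that running median; the amplitudes at the affected beats are
replaced by their own running median, a symmetric treatment that can be
disabled (`clean_amp = FALSE`). Replacement by the local median makes the
operation idempotent in practice, which the test suite checks on random
series with isolated outliers.

**Windowing** (`resample_window()`, `build_windows()`) uses 0-based
minutes and half-open spans in seconds: minute *m* covers [60m, 60(m+1)).
A window spans [60(m−2), 60(m+3)) and is resampled by natural cubic
splines, as functions of *beat time*, onto 900 uniform points (an
effective 3 Hz grid over 300 s). Three numerical choices matter:

* interpolation is over beat time, not beat index — the channels then
  represent a uniformly sampled tachogram;
* because an RR interval is attributed to the *later* beat, the knots
  are the beats inside the window that carry an RR value, and at least
  four are required (a cubic needs four support points); windows with
  fewer raise a typed `apnea_sparse_beats` condition and are dropped,
  as are edge minutes without full ±2-minute context — no padding;
* grid points outside the knot range are clamped to the nearest knot
  value rather than extrapolated.

**Channel normalization** is a per-channel z-score whose mean/SD are
computed on the training windows and stored inside the fitted model, so
inference on new recordings is self-contained.

## The classifier

The network input is a 900×2 array. The stack is: a stem convolution;
`n_blocks` *spatio-temporal blocks*, each 1-D convolution (128 filters,
kernel 3, ReLU, "same" padding) → max-pooling (kernel = stride = 3,
trailing remainder dropped) → dropout → bidirectional GRU (128 units per
direction); between blocks the forward and backward stacks are
concatenated along the channel axis, after the last block they feed a
dot-product attention layer `a = softmax(F Bᵀ) B`; then
flatten → dense(64, ReLU) → dropout → dense(64, ReLU) → dense(2,
softmax). All dropout rates are 0.2. With "same" convolutions and pool 3
the sequence lengths are 900 → 300 → 100 → 33, and the builder asserts
this algebra, refusing configurations whose sequence length would
collapse below one step. The default of three blocks follows the
block-count tuning that maximises F1; the count is a plain argument
(`model_spec(n_blocks = ...)`).

The GRU follows the gate convention in which the *update* gate scales
the previous state: `h⟨t⟩ = z h⟨t−1⟩ + (1−z) h̃⟨t⟩`, with
`r = σ(W_r x + U_r h)`, `z = σ(W_z x + U_z h)` and
`h̃ = tanh(W_x x + r ⊙ (U_x h))`. The mirrored convention used by some
frameworks is equivalent under z ↔ 1−z; we implement the literal form.
The attention softmax is taken over key positions (rows of F Bᵀ), the
natural reading when the output is a mixture of backward states. The
reference equations are bias-free; the trainable layers carry biases
initialised to zero, a standard relaxation that changes nothing at
initialisation.

Because no deep-learning framework is involved, the package contains two
independent renderings of every layer: literal per-equation reference
operations (`conv1d()`, `max_pool()`, `gru_step()`, `bigru_run()`,
`dot_attention()`) and a batched engine with hand-derived
backpropagation (including full backpropagation through time for the
BiGRU and the softmax Jacobian of attention). The test suite checks the
engine against the reference ops, the reference ops against brute-force
loops, and the analytic gradients against central finite differences.
One subtlety: with all-zero bias initialisation a ReLU pre-activation
can sit exactly on its kink (everything upstream dead), where finite
differences see slope ½ while the engine uses the conventional
subgradient 0; gradient tests therefore nudge biases off zero.
Max-pooling ties route the gradient to the earliest position.

## Training

`train()` implements seeded mini-batch training: shuffle, forward,
binary cross-entropy (probabilities clipped at 1e-7), backward, and a
bias-corrected Adam step
`θ ← θ − α·√(1−β₂ᵗ)/(1−β₁ᵗ) · m/(√v + ε)` with α = 0.001,
batch 128, β₁ = 0.9, β₂ = 0.999, ε = 1e-7, 40 epochs by default. After
every epoch the validation accuracy is computed in inference mode and
the weights are checkpointed whenever it improves; ties keep the earlier
checkpoint, and the returned model carries the best one. Accuracy is the
checkpoint criterion because it is the headline per-segment metric;
with `epochs = 0` the initial weights come back unchanged, which makes
`finetune()` — the same loop started from pretrained weights — exact at
the boundary.

When `apnea_net()` splits its own validation set it does so by *whole
recording* with a seeded assignment. Adjacent windows overlap by four of
their five minutes, so a segment-level split would leak most of each
validation window into training; recording-level splitting avoids that.
For a second, imbalanced cohort the workflow is
`split_windows()` (seeded 8:1:1, stratified at segment granularity or
leakage-free at recording granularity), `oversample_minority()`
(duplicate minority windows until the classes balance), and
`finetune()` from the weights trained on the first cohort.

## Evaluation

`confusion_metrics()` computes accuracy, recall, specificity, precision
and F1 with the apneic class positive; undefined ratios are reported as
`NaN`, never silently zero. `roc_auc()` is the rank-statistic AUC (ties
counted ½), which equals trapezoidal integration of the empirical ROC
curve — both identities are asserted in the tests, along with agreement
with the pROC package. The decision threshold for hard calls is fixed at
0.5 (the softmax argmax); only the ROC sweep varies it.

Per recording, `evaluate_recording()` computes AHI = 60·N/T and calls SA
strictly above 5 events/hour. T counts the minutes that survived
preprocessing — predictions exist only for those — and the same
convention is applied to the reference AHI when both are derived from
one recording; with very sparse dropouts the two conventions differ
negligibly, but both can be computed from the returned objects.
`cohort_mae_corr()` reports the mean absolute error and Pearson
correlation of predicted versus reference AHI over a cohort, with a
warning and `NA` correlation when either side has zero variance.

## The synthetic generator

`generate_dataset()` exists so that every stage is testable without
clinical downloads. It models exactly the structure the classifier's two
channels can see, and nothing else: outside apnea episodes RR intervals
are Normal(0.85 s, 0.02 s); inside an episode the RR mean is modulated
by `1 + 0.25·sin(2πt/40 s)` — a 40 s bradycardia–tachycardia cycle —
and the R-amplitude (1 mV baseline, 0.02 mV beat-to-beat jitter) by a
30 % swing at the same phase. Beats are rendered as a biphasic QRS-like
template about 100 ms wide whose unit peak lands exactly on the beat
sample, plus 0.05 mV Gaussian noise; records are written as WFDB
format-16 files with plain-text per-minute annotations and a JSON
manifest of the full ground truth. Per-minute labels are derived from
the episode list by the same strict >5 s occupancy rule used for
polysomnogram event tables, so the generator and the event labeler are
cross-checked against each other. Episode lengths are uniform on
120–300 s and gaps are scaled so that the *labeled-minute* prevalence
(not the raw time fraction, which the >5 s rule inflates at episode
boundaries) hits the configured target, 0.3 by default. All randomness
derives from one master seed via fixed per-record offsets, so any record
is independently reproducible.

What the generator deliberately omits: realistic ECG morphology (P/T
waves), arrhythmias and ectopy, electrode artefacts and baseline wander,
respiration or SpO₂ dynamics, and inter-subject variability beyond the
seeded episode layout. Passing the synthetic end-to-end check therefore
demonstrates that the mechanics of the pipeline — detection, cleaning,
windowing, optimisation, calibration of the whole chain — are sound; it
does not certify clinical performance, which must be established on real
recordings.

## Problem sizes used in the checks

The synthetic end-to-end check simulates eight 30-minute recordings
(about 17,000 beats, 208 windows), trains the small one-block
configuration (8 filters, 8 GRU units, dropout 0.2) for 5 epochs with
learning rate 0.01 and batch 16 — rates matched to a training set of
~150 windows, where the 0.001/128 defaults are matched to cohorts a
hundred times larger — and evaluates on two held-out recordings; the
per-recording cohort adds six single-recording cohorts spanning target
prevalences 0.05–0.55 so that reference AHI varies enough for a
meaningful correlation. These sizes are the package's own choice of a
small but non-trivial study; larger cohorts only sharpen the same
statistics.

## Known limitations

* The detector is tuned for adult QRS morphology at 100–128 Hz; very low
  sampling rates coarsen the ±50 ms refinement grid.
* Training is CPU-bound R; the default three-block model at full
  clinical scale (tens of thousands of windows, 40 epochs) is intended
  to be run via the CLI on a machine with time to spare, not inside a
  test suite.
* Dropout is the only regulariser, as specified; there is no early
  stopping beyond best-checkpointing, no learning-rate schedule, and no
  class-weighted loss (oversampling is the supported mechanism).
* EDF support covers 16-bit uncompressed signals without EDF+
  annotations; respiratory events come from plain-text tables, with the
  event types that count toward a minute's label configurable
  (`include_types`), defaulting to all listed events.
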