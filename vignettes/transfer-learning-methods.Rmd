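---
title: "Layer-freezing transfer learning for EEG and ECG classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-freezing transfer learning for EEG and ECG classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette describes the models and procedures the package implements, the
choices that were genuinely open, and what the bundled synthetic generators do
and do not establish.

## The two classification problems

**Seizure-state classification.** Multichannel scalp EEG (29 channels in a
10-20 montage, 512 Hz) with annotated seizure onsets is conditioned in three
steps: per-channel linear detrending, a 0.5-50 Hz zero-phase bandpass, and
reduction to a single channel by global field power,

$$\mathrm{GFP}(t) = \sqrt{\frac{1}{N}\sum_{i=1}^{N}\bigl(x_i(t) - \bar x(t)\bigr)^2},$$

the per-sample standard deviation across the $N$ channels. The GFP trace is
cut into 10-s windows with 8-s overlap, and each window is labeled by where
it falls relative to the next seizure onset $T$: *interictal* (after the
previous seizure and at least 50 min before $T$), or one of three preictal
bands, $[T-2400, T-1800)$, $[T-1800, T-1200)$ and $[T-1200, T-600)$ seconds
(40-30, 30-20, 20-10 min before onset). Windows straddling a state boundary
are dropped rather than majority-labeled, which trades a few windows for
label purity. Each preictal band is classified against interictal with a
1D CNN (four conv/batch-norm/max-pool stages, global average pooling, three
dense layers, 2-way softmax; `seizure_model_spec()`).

**Sleep staging and EEG-to-ECG transfer.** Single-channel EEG (100 Hz) or
single-lead ECG (256 Hz, resampled to 100 Hz) is cut into 30-s windows with
22.5-s overlap; windows entirely inside a run of identically scored 30-s
epochs inherit that stage (R&K codes are first mapped to AASM, merging S3
and S4 into N3). The five-stage classifier (`sleep_model_spec()`) has three
named blocks - two conv(5)/BN pairs plus average pooling in blocks 1-2, one
conv/BN plus global average pooling in block 3 - followed by dense 32 and a
5-way softmax. Transfer pretrains this network on EEG, freezes a contiguous
prefix of blocks, and retrains the rest on ECG.

Both architectures use *valid* (unpadded) convolutions and poolings with
`out_len = floor((in_len - k)/stride) + 1`; this is the only padding choice
that reproduces the published per-layer output lengths, which
`infer_shapes()` computes in closed form and the test suite compares against
a live forward pass.

## The training engine

No deep-learning framework is involved: the package ships a compact,
purpose-built engine (R orchestration over C++ kernels) implementing 1D
convolution via chunked im2col + BLAS, max/average/global pooling, batch
normalization with fused ReLU, dense layers, softmax cross-entropy, and Adam.
Gradient correctness is pinned by finite-difference tests at every layer
kind. Training is single-threaded deterministic given a seed.

Hyperparameters follow the published configurations: Adam with batch 128;
learning rate 2e-4 (floor 1e-5) for the seizure model and 1e-3 (floor 1e-4)
for the sleep model, halved after 5 epochs without validation-loss
improvement; early stopping with patience 10 where enabled (the sleep
experiment by default). Unstated details were fixed once: ReLU hidden
activations, He-normal initialization, reduce-on-plateau factor 0.5, maximum
100 epochs.

Two numerical choices deserve mention:

* **Batch-norm recalibration.** Running means/variances collected as
  exponential averages during training lag behind the drifting convolution
  weights; on spiky inputs (ECG) the mismatch between train-time batch
  statistics and eval-time running statistics was large enough to collapse
  held-out predictions to a single class. `fit_network()` therefore closes
  with one exact pass over the training data that recomputes the running
  statistics under the final weights. Frozen batch-norm layers are excluded:
  they keep their source-domain statistics and run in inference mode, which
  is how "weights were fixed" is interpreted here.
* **Zero-phase filtering.** Butterworth filters (order 4) are applied
  forward-backward so window labels stay aligned with samples. The bandpass
  is realized as a highpass/lowpass cascade: a direct high-order bandpass
  with a 0.5 Hz edge at 512 Hz (normalized 0.002) is numerically unstable,
  while the cascade is stable and matches the direct 4th-order response to
  within a percent. An order-4 zero-phase bandpass attenuates a 60 Hz tone
  to about 17% RMS (the tests pin this measured value); sharper stopbands
  would need higher order than is safe at this edge.

## Freezing semantics

`freeze_spec()` expresses the two published protocols: the seizure network's
12 pre-global feature layers (4 x conv/BN/pool) are frozen as a prefix of
length 3, 6, 9 or 12 - each admissible depth lands on a stage boundary - and
the sleep network's blocks are frozen contiguously from `block_1`. Frozen
layers are excluded from Adam updates (their reported gradients are zero),
and frozen parameters are asserted bit-identical after fine-tuning. Trainable
parameter counts are strictly decreasing along both freezing sequences.

## What the synthetic generators emulate

The source study gives no generative model for its data, so the generators
encode the *statistical structure the analysis assumes*, with fixed,
documented defaults; they aim at class separability, not physiology.

* **Seizure EEG** (`generate_seizure_recording()`): every channel is 1/f
  (pink) background noise plus white noise at 3 dB SNR. Each preictal band
  adds a sinusoid at a distinct center frequency and amplitude (4 Hz/1.0,
  8 Hz/1.5, 16 Hz/2.0 for the 40-30, 30-20, 20-10 min bands) with a random
  per-channel gain, so the oscillation survives the GFP reduction as both a
  level and a rhythm cue. Onsets closer than 40 min to the recording start
  are allowed and flagged (`truncated_preictal`).
* **Sleep EEG** (`generate_sleep_recording()`, EEG modality): per-epoch
  stage rhythms over the same background: W 10 Hz (amp 1.5), N1 5.5 Hz
  (1.2), N2 adds 13 Hz spindle bursts (1-s Gaussian envelopes every 3 s),
  N3 1 Hz at amplitude 3, REM mixed 4.5/7.5 Hz at low amplitude.
* **Sleep ECG** (ECG modality): a Ricker-wavelet QRS train whose per-beat
  rate is drawn from the stage's mean and spread (W 75±5, N1 70±4, N2 65±3,
  N3 58±2, REM 72±8 beats/min), over the same 1/f-plus-white background.
  Stage information is carried by beat rate and variability only, so W and
  REM (75±5 vs 72±8) overlap substantially - by design the ECG task is much
  harder than the EEG task, which mirrors the published gap between the two
  modalities.
* **Hypnograms** (`generate_hypnogram()`): a first-order Markov chain over
  the five stages with a diagonally dominant transition matrix
  (`hypnogram_transition_matrix()`), starting in wake. Because the chain is
  genuinely stochastic, the presence of all five stages in a short record
  is highly probable but not certain; the tests check it at fixed seeds.

What passing these benchmarks shows: the full pipeline - generation,
conditioning, windowing, labeling, balancing, splitting, training,
freezing, evaluation - is wired correctly and the networks can learn
band-power-coded classes on a CPU in minutes. What it does not show:
performance on real polysomnography or scalp EEG, which contains artifacts,
non-stationarity, inter-subject variability and class imbalance that these
generators deliberately omit. The published real-data accuracy tables are
out of reach of any synthetic benchmark and are not reproduced here.

## Problem sizes

Desk-scale defaults keep every run CPU-friendly: 200 windows per state
(versus 12,222 and 16,000 in the source cohorts), at most 20 training
epochs for the learnability benchmarks, 10-fold (seizure) and 5-fold
(sleep) cross-validation with one trained fold by default
(`train_folds = 1`), and the transfer benchmark fine-tuning on 10% of the
ECG training windows over five seeds with up to 40 epochs (early stopping,
patience 10) for both the fine-tuned and the from-scratch arm. All of
these are configuration values (`experiment_config()`), not hard limits.

On the transfer benchmark the direction matches the source study - the
block_1-frozen model's mean test accuracy edges out from-scratch training
on the reduced ECG set - but the margin is small, for two structural
reasons the generators make explicit: the sleep network is tiny (freezing
block_1 fixes under 10% of its parameters, so the regularization effect is
weak), and synthetic EEG rhythms share only the 1/f background with the
synthetic QRS trains, so pretrained mid-level features must be relearned.
Fine-tuning therefore needs a few dozen epochs before it overtakes; with
very short budgets scratch training can win. Nothing quantitative about
real-data transfer gains should be read into this benchmark.

## Known limitations

* The interictal definition measures from the previous seizure *onset*
  plus a configurable offset (default 0) because seizure ends are not
  annotated; the tail after the last seizure is left unlabeled.
* EDF support covers what the fixtures and the four public datasets need
  (16-bit signals, per-signal rates, name-based channel selection), not the
  full EDF+ specification; annotations travel in a documented
  onset/duration/label text dialect.
* The engine is deliberately minimal: no GPU, no padding modes other than
  valid, no dropout. Adding them would be straightforward but nothing in
  the reproduced procedures needs them.
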