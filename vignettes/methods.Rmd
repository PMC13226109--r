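---
title: "Staging disordered sleep from EEG alone: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging disordered sleep from EEG alone: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why a three-class, EEG-only stager

In REM sleep behavior disorder the atonia that normally silences muscle
activity during REM is lost. High-frequency activity contaminates REM
EEG, bouts shorten, and transitions multiply, so the REM-wake boundary —
already the hardest decision in automated staging — becomes the dominant
error mode. `somnifuse` therefore stages Wake/NREM/REM only (no NREM
substages), from eight routinely recorded EEG channels (Fp1, Fp2, C3, C4,
O1, O2, A1, A2), and treats whole-night REM% and NREM% of total sleep
time as the clinically consumed output: misclassifications concentrated
at stage boundaries largely cancel in these aggregates.

## Signal conditioning

Each recording passes a fixed chain: band-pass filter, wavelet denoise,
resample to 100 Hz, cut into 30-s epochs, screen artifacts.

* **Band-pass 0.5–35 Hz.** Realized as an order-4 Butterworth high-pass
  at 0.5 Hz plus an order-8 Butterworth low-pass at 35 Hz, both applied
  forward–backward (zero phase). A single 4th-order band-pass run twice
  would lose ~2.2 dB at 30 Hz; the split design keeps the pass-band flat
  to ±1 dB over 1–30 Hz while attenuating 0.1 Hz drift and 45 Hz noise by
  far more than 20 dB. The filter response contract is tested directly.
* **Wavelet denoising.** Periodized Daubechies-4 decomposition to level 5,
  soft thresholding of all detail coefficients at the universal threshold
  `σ√(2 log N)` with `σ = MAD(finest detail)/0.6745`. This is the
  canonical VisuShrink recipe: on a noiseless smooth signal the estimated
  `σ` collapses and the transform is essentially the identity; at 5 dB SNR
  it strictly reduces RMSE to the clean signal (tested). The DWT is a
  compact periodized filter bank implemented in the package; perfect
  reconstruction is asserted to 1e-10.
* **Resampling** runs after filtering at native rate (the 35 Hz cut-off
  doubles as the anti-aliasing filter) via polyphase FIR resampling.
  Upsampling is refused — the 100 Hz model rate is a ceiling, not a target
  to interpolate toward.
* **Artifact screening** flags an epoch when any channel exceeds 500 µV
  absolute amplitude, falls below 0.01 µV² variance (flat line), or
  carries more than half as much power above 35 Hz as within 0.5–35 Hz.
  The thresholds are package defaults exposed in `preprocess_config()`,
  not clinical constants. Flagged epochs are excluded from training but
  still predicted (with a warning) at inference, since a clinical user
  still needs a label for every epoch.

## The three representations

* **Raw stream:** the 8 × 3000 waveform, z-scored per epoch and channel so
  the CNN sees morphology rather than absolute amplitude.
* **Spectrogram stream:** per channel, an STFT with a 128-sample Hann
  window and 32-sample hop (≈0.78 Hz × 0.32 s resolution), log-compressed
  as `log10(power + 1e-10)`, restricted to 0.5–35 Hz, bilinearly resized
  to 32 × 32 and z-normalized per channel. Window, hop, ε and the resize
  kernel are declared choices pinned in `spectrogram_config()`.
* **Handcrafted stream:** 65 features = 8 channels × (mean, SD, RMS,
  and relative Welch band powers in delta/theta/alpha/beta/low-gamma) + the
  channel-mean SEF90. Variance is omitted as exactly redundant with SD,
  which is what makes the count come out to 65; the layout is versioned in
  `feature_names()` so alternatives can be swapped. Relative (not
  absolute) band powers make the spectral block amplitude-invariant across
  recordings; Welch uses 4-s Hann segments at 50% overlap so the 0.25 Hz
  grid resolves the 0.5 Hz delta edge. Degenerate epochs (total in-band
  power < 1e-12 µV²) yield zeros plus a flag instead of NaN, and SEF90
  then reports the lower band edge.

## The network

Both CNN streams use three conv–batchnorm–ReLU–maxpool blocks and global
average pooling into 64-d embeddings: raw 8→32→64→64 channels (kernels
7/5/3, first conv stride 4, pools of 4) and spectrogram 8→16→32→64 (3×3
kernels, 2×2 pools). The stride-4 front end on the waveform keeps
single-CPU training fast at no accuracy cost on separable data; it is the
one structural liberty taken beyond "three blocks, global aggregation,
64-d output". Concatenating 64 + 64 + 65 gives the 193-d fused vector
(asserted at construction), gated feature-wise by
`σ(W₂ relu(W₁ z))` with a 96-unit hidden layer, then classified by dense
layers 193→128→64→3 with dropout 0.5/0.3 and a softmax.

Training: Adam at 0.001 on weighted cross-entropy (`w_c = N/(3N_c)`, so
balanced data reduces to plain cross-entropy — asserted to machine
precision), batch 64, reduce-on-plateau (×0.5 after 3 stagnant validation
epochs), early stopping and checkpoint selection on validation macro-F1.
The selection metric, gate width, dropout rates and scheduler constants
are declared package choices; the dimension chain and optimizer settings
are structural. Handcrafted features are z-scored with statistics from
the training epochs only; the internal validation split is subject-wise
(20% of development subjects, at least one), so no subject influences
both gradient updates and selection. Every random draw — initialization,
shuffling, dropout, splits — derives from the single config seed, and two
runs with one seed are bit-identical.

All backpropagation is implemented in the package (im2col convolutions,
pooling and batch-norm in compiled code) and verified against central
finite differences at 1e-3 relative tolerance over every parameter
tensor.

## Cross-validation and evaluation

`msfnet_cv()` assigns whole subjects to 5 folds, trains on 4, tests on
the held-out fifth, and pools held-out predictions: each epoch is scored
by a model that never saw its subject in training, early stopping or
selection, and the absence of subject overlap is a hard assertion, not a
convention. Pooled metrics are per-class precision/recall/F1 from the
3×3 confusion matrix; a class-balanced display subset (the conventional
463 per class, 1389 total) can be drawn for visualization without
majority-class dominance.

Night-level agreement uses TST = 0.5 min × (#NREM + #REM epochs), REM% =
100·REM/(NREM+REM), NREM% = 100 − REM%. A sleepless night is flagged
rather than propagating NaN. Bland–Altman limits use the n−1 SD;
ICC(A,1) is computed from the two-way ANOVA mean squares with
McGraw–Wong F-based intervals and is cross-checked against an `aov()`
oracle to 1e-9. Because NREM% ≡ 100 − REM%, the NREM agreement report is
the exact sign-mirror of the REM report, which the tests assert.

Associations: Spearman with midranks and the t approximation (exact
permutation available for n ≤ 10), Benjamini–Hochberg FDR across exactly
the family of correlations submitted in one call (the family is
caller-defined and logged in the report), and OLS with z-scored outcome
and continuous predictors. Note that with a z-scored outcome an exactly
linear relation has standardized β = 1 regardless of the raw slope;
binary covariates (sex, medication as one 0/1 indicator) stay
unstandardized, marked in the output.

## The synthetic cohort

The generator is the package's study-condition definition, not a tuning
surface. Hypnograms are first-order Markov chains with self-transitions
≥ 0.88; the NREM→REM entry rate is solved from a per-subject target REM
share (drawn N(0.18, 0.07), truncated to 4–40%), emulating the reduced
and variable REM fraction of disordered sleep. EEG epochs are sums of
1/f background and band-limited Gaussian components: wake alpha (8–13 Hz)
with 1.8× occipital weighting, NREM delta (0.5–4 Hz, frontal-weighted)
plus burst-gated 11–15 Hz central spindles, REM theta (4–8 Hz) with
20–35 Hz burst contamination at probability 0.3 — the lost-atonia
analogue; raising that probability provably raises REM low-gamma power.
Scale scores are linear in true REM% plus Gaussian noise, rounded and
clipped to instrument ranges (PSQI 0–21, ESS 0–24, RBDSQ 0–13), with
slopes calibrated once so the population Spearman correlation is ≈ −0.5
(PSQI analogue), ≈ −0.45 (RBDSQ) and 0 (ESS) at the generator's
between-subject REM% spread.

What the generator does *not* emulate: real scalp topography and volume
conduction, EOG/EMG crosstalk, apnea and arousal microstructure,
scorer disagreement, or night-time nonstationarity. Its stages are
deliberately well-separated in spectral space — a passing cross-validation
here demonstrates that the pipeline is correct and leak-free, not that it
reaches clinical accuracy on real PSG.

## Problem sizes and numerical choices

The standard test-bench cohort is 10 subjects × 240 epochs (2,400 epochs,
two simulated hours per subject), trained for up to 4 epochs per fold —
on this separable benchmark validation macro-F1 saturates within the
first epoch, so longer schedules only add runtime. The fitting default
(`max_epochs = 30`, patience 10) is meant for harder data. Association
experiments use n = 44 subjects and 100 seeded replicates. Epoch argmax
ties break toward the lowest class index (Wake first); zero-denominator
precision/recall report 0 with a flag; the ε-guards are 1e-12 µV² (band
power), 1e-10 (log spectrogram) and 1e-8 (z-scoring).

## Known limitations

Three-class only, EEG-only (no RSWA detection, no diagnosis); artifact
*correction* is out of scope (removal only); the 65-feature layout is a
declared reconstruction of a feature-family description, versioned so it
can be swapped; the compiled kernels are plain single-threaded im2col —
adequate for the bench sizes here, not for large clinical corpora.
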