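# somnifuse

Three-class EEG sleep staging by multi-stream gated fusion, aimed at REM
sleep behavior disorder (RBD).

## The problem

RBD is defined by the loss of normal REM muscle atonia: EMG-like
high-frequency activity leaks into REM periods, sleep is fragmented, and
the canonical electrophysiological contrast between REM and quiet
wakefulness collapses. Automated sleep stagers trained on healthy cohorts
degrade exactly there, at the REM–wake boundary. Yet the quantities
clinicians act on — whole-night REM% and NREM% of total sleep time (TST) —
are aggregates over hundreds of 30-s epochs and can remain reliable even
when individual boundary epochs are ambiguous.

`somnifuse` implements, end to end and EEG-only (8 channels: Fp1, Fp2, C3,
C4, O1, O2, A1, A2):

1. **Signal conditioning** — zero-phase 0.5–35 Hz band-pass filtering,
   Daubechies-4 wavelet soft-threshold denoising
   (threshold `σ·sqrt(2·log N)`, `σ = MAD(d₁)/0.6745`), polyphase
   resampling to 100 Hz, 30-s epoching, and statistical artifact screening
   (amplitude / flat-line variance / high-frequency power ratio).
2. **Three epoch representations** — the raw `8 × 3000` waveform; an
   `8 × 32 × 32` log-power STFT spectrogram tensor; and a 65-dimensional
   handcrafted vector (per channel: mean, SD, RMS and relative Welch band
   powers in δ 0.5–4, θ 4–8, α 8–13, β 13–30 and low-γ 30–35 Hz; plus the
   channel-mean spectral edge frequency SEF90).
3. **The staging network** — two small CNN encoders (3 conv–norm–ReLU–pool
   blocks each, global average pooling) produce 64-d embeddings of the raw
   and spectrogram streams; concatenated with the 65 handcrafted features
   they form a 193-d vector `z` that a two-layer gating MLP reweights as
   `u = σ(W₂ relu(W₁ z)) ⊙ z` before a three-layer dropout classifier
   emits P(Wake), P(NREM), P(REM). Training uses Adam (lr 0.001), weighted
   cross-entropy with `w_c = N/(3 N_c)`, a reduce-on-plateau schedule, and
   checkpoint selection on validation macro-F1 — all under **patient-wise
   five-fold cross-validation** (every epoch of a subject stays in one
   fold; test folds never touch training, early stopping or selection).
4. **Clinical translation** — whole-night TST, REM% and NREM% of TST;
   Bland–Altman bias and 95% limits of agreement, MAE, and ICC(A,1)
   (two-way model, absolute agreement, single measurement, McGraw–Wong
   confidence intervals); Spearman correlations of REM% with clinical
   scales (PSQI/ESS/RBDSQ-like) under Benjamini–Hochberg FDR, and
   covariate-adjusted standardized regressions.
5. **A synthetic PSG generator** — Markov-chain hypnograms, stage-
   conditioned 1/f + band-limited EEG (occipital alpha in wake, frontal
   delta and central spindle bursts in NREM, theta REM with 20–35 Hz
   "lost-atonia" contamination bursts), injected artifacts, and clinical
   scales with planted monotone dependence on REM% — so the entire system
   is testable with no clinical data.

## Worked example

```r
library(somnifuse)

# a small synthetic cohort: 5 subjects x 48 epochs, REM-rich dynamics
cohort <- simulate_cohort(sim_config(n_subjects = 5, epochs_per_night = 48,
                                     rem_target_mean = 0.3, seed = 41))
ds <- build_epoch_dataset(cohort)   # conditioning + all three streams
ds
#> <epoch_dataset> 240 epochs from 5 subjects (239 usable)

cv <- msfnet_cv(ds, k = 5, config = msfnet_config(max_epochs = 3, seed = 5))
cv
#> Patient-wise 5-fold cross-validation: 240 pooled out-of-fold epochs from 5 subjects
#> Epoch-level metrics (n = 240, accuracy 0.963, macro-F1 0.959)
#>  stage precision recall    f1 support
#>   Wake     0.885  0.964 0.923      56
#>   NREM     1.000  0.945 0.972     127
#>    REM     0.966  1.000 0.983      57
```

Per-class precision/recall/F1 come from the pooled out-of-fold confusion
matrix: each subject is predicted only by the fold model that never saw it
in training, early stopping or model selection. Night-level use of a
frozen model on a new recording:

```r
fit <- msfnet(list(raw = ds$raw, spec = ds$spec, feat = ds$feat),
              ds$y, subjects = ds$subject,
              config = msfnet_config(max_epochs = 8, seed = 5))
set.seed(909)
night <- simulate_recording(sim_config(epochs_per_night = 120), "night1")
staged <- predict_recording(fit, night$recording)
night_summary(staged$hypnogram)   # automated
#> <night_summary> 'night1': TST 51.0 min, REM 3.9%, NREM 96.1% of TST
night_summary(night$hypnogram)    # ground truth
#> <night_summary> 'night1': TST 49.5 min, REM 1.0%, NREM 99.0% of TST
```

A thin CLI over the same functions lives at `inst/cli/somnifuse`
(`simulate`, `train-cv`, `apply`, `agree`, `associate`).

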