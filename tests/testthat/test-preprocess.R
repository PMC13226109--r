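make_rec <- function(x, rate = 200, channels = 1) {
  sig <- matrix(rep(x, each = channels), channels, byrow = FALSE)
  sig <- matrix(x, nrow = channels, ncol = length(x), byrow = TRUE)
  recording(sig, rate, paste0("C", seq_len(channels)), "t")
}

test_that("band-pass filter passes 10 Hz within 1 dB and kills slow drift", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  sine <- sin(2 * pi * 10 * t)
  out <- bandpass_filter(make_rec(sine, fs))$signals[1, ]
  rms_ratio_db <- 20 * log10(sqrt(mean(out^2)) / sqrt(mean(sine^2)))
  expect_lt(abs(rms_ratio_db), 1)

  drift <- sin(2 * pi * 0.05 * t)
  outd <- bandpass_filter(make_rec(drift, fs))$signals[1, ]
  mid <- (15 * fs):(45 * fs)   # steady-state portion
  atten_db <- 20 * log10(sqrt(mean(drift[mid]^2)) / sqrt(mean(outd[mid]^2)))
  expect_gt(atten_db, 20)

  # 45 Hz noise attenuated by at least 20 dB too
  hf <- sin(2 * pi * 45 * t)
  outh <- bandpass_filter(make_rec(hf, fs))$signals[1, ]
  expect_gt(20 * log10(sqrt(mean(hf[mid]^2)) / sqrt(mean(outh[mid]^2))), 20)

  zero <- bandpass_filter(make_rec(rep(0, fs * 40), fs))$signals[1, ]
  expect_equal(zero, rep(0, fs * 40))

  expect_error(bandpass_filter(make_rec(sine, 60)), "too low")
})

test_that("wavelet denoising reduces RMSE on a noisy sine and is benign otherwise", {
  fs <- 100
  t <- (0:(30 * fs - 1)) / fs
  clean <- sin(2 * pi * 2 * t)
  set.seed(99)
  snr_db <- 5
  noise_sd <- sqrt(mean(clean^2) / 10^(snr_db / 10))
  noisy <- clean + rnorm(length(clean), sd = noise_sd)
  den <- dwt_denoise(make_rec(noisy, fs))$signals[1, ]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))

  zero <- dwt_denoise(make_rec(rep(0, 3200), fs))$signals[1, ]
  expect_equal(zero, rep(0, 3200))

  # noiseless smooth signal: MAD of finest details ~ 0, so threshold ~ 0
  smooth <- dwt_denoise(make_rec(clean, fs))$signals[1, ]
  expect_lt(max(abs(smooth - clean)), 0.05)

  expect_error(dwt_denoise(make_rec(noisy, fs),
                           preprocess_config(wavelet = "sym8")), "wavelet")
})

test_that("the periodized DWT reconstructs perfectly", {
  set.seed(5)
  x <- rnorm(1024)
  dec <- somnifuse:::.dwt_decompose(x, 5)
  expect_equal(somnifuse:::.dwt_reconstruct(dec), x, tolerance = 1e-10)
})

test_that("resampling reaches exactly the model rate and preserves spectra", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  sine <- sin(2 * pi * 10 * t)
  rs <- resample_to_model_rate(make_rec(sine, fs))
  expect_equal(rs$rate, 100)
  expect_equal(ncol(rs$signals), 6000)
  # spectral peak still at 10 Hz
  ep <- rs$signals[1, 1:3000]
  psd <- welch_psd(ep, 100)
  expect_equal(psd$freq[which.max(psd$power)], 10)

  already <- make_rec(sine[1:3000], 100)
  expect_identical(resample_to_model_rate(already)$signals, already$signals)

  expect_error(resample_to_model_rate(make_rec(sine, 80)), "upsampling")
})

test_that("artifact screening flags amplitude, flat-line and spectral faults", {
  set.seed(8)
  coh <- small_cohort_dataset()$cohort
  rec <- coh$subjects[[2]]$recording
  cfg <- preprocess_config()
  # clean generator epochs (no artifact injection) are all usable
  clean <- simulate_recording(sim_config(epochs_per_night = 6, artifact_rate = 0,
                                         seed = 3), "clean")
  eps <- epoch_signals(clean$recording)
  qc <- detect_artifacts(eps, cfg)
  expect_true(all(qc$usable))

  # one channel scaled to 10x the amplitude limit
  big <- clean$recording
  big$signals[3, 1:3000] <- big$signals[3, 1:3000] *
    (10 * cfg$amplitude_limit / max(abs(big$signals[3, 1:3000])))
  qc2 <- detect_artifacts(epoch_signals(big), cfg)
  expect_false(qc2$usable[1])
  expect_match(qc2$reason[1], "amplitude")

  flat <- clean$recording
  flat$signals[, 1:3000] <- 0
  qc3 <- detect_artifacts(epoch_signals(flat), cfg)
  expect_match(qc3$reason[1], "variance")

  # usable count is monotone non-increasing as the amplitude limit falls
  counts <- vapply(c(500, 200, 100, 50, 20), function(lim)
    sum(detect_artifacts(eps, preprocess_config(amplitude_limit = lim))$usable),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the conditioning chain is deterministic and per-channel", {
  set.seed(12)
  rec <- recording(matrix(rnorm(8 * 200 * 31, sd = 20), 8), 200,
                   canonical_montage(), "det")
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$qc, b$qc)

  # permuting channels permutes outputs identically
  perm <- c(3, 1, 2, 5, 4, 7, 8, 6)
  rec_p <- recording(rec$signals[perm, ], 200, canonical_montage(), "det")
  c <- preprocess_recording(rec_p)
  expect_equal(c$epochs$data[, 1, ], a$epochs$data[, perm[1], ])
  expect_equal(c$epochs$data[, 4, ], a$epochs$data[, perm[4], ])
})
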