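test_that("time statistics match hand computations", {
  expect_equal(time_stats(rep(5, 10)), c(mean = 5, sd = 0, rms = 5))
  expect_equal(time_stats(c(1, -1, 1, -1)),
               c(mean = 0, sd = sqrt(4 / 3), rms = 1), tolerance = 1e-7)
  expect_equal(time_stats(rep(0, 4)), c(mean = 0, sd = 0, rms = 0))
  expect_error(time_stats(1), "at least 2")
})

test_that("Welch PSD localizes tones and handles degenerate input", {
  fs <- 100
  t <- (0:(30 * fs - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(psd$freq[which.max(psd$power)], 10)
  expect_true(all(psd$power >= 0))
  expect_equal(range(psd$freq), c(0, 50))

  zero <- welch_psd(rep(0, 3000), fs)
  expect_true(all(zero$power == 0))
  expect_error(welch_psd(rep(0, 2999), fs), "3000 samples")

  # Parseval expectation for white noise: in-band power ~ var * 34.5/50
  set.seed(123)
  ratio <- replicate(40, {
    x <- rnorm(3000)
    p <- welch_psd(x, fs)
    df <- p$freq[2] - p$freq[1]
    sum(p$power[p$freq >= 0.5 & p$freq <= 35]) * df / var(x)
  })
  expect_lt(abs(mean(ratio) - 34.5 / 50), 0.2 * 34.5 / 50)
})

test_that("relative band powers concentrate on the stimulated band and sum to one", {
  fs <- 100
  t <- (0:(30 * fs - 1)) / fs
  alpha <- relative_band_powers(welch_psd(sin(2 * pi * 10 * t), fs))
  expect_gte(alpha[["rel_alpha"]], 0.95)
  delta <- relative_band_powers(welch_psd(sin(2 * pi * 2 * t), fs))
  expect_gte(delta[["rel_delta"]], 0.95)
  expect_equal(unname(relative_band_powers(welch_psd(rep(0, 3000), fs))),
               rep(0, 5))
  set.seed(7)
  for (i in 1:20) {
    rb <- relative_band_powers(welch_psd(rnorm(3000), fs))
    expect_equal(sum(rb), 1, tolerance = 1e-6)
    expect_true(all(rb >= 0 & rb <= 1))
  }
})

test_that("SEF90 follows the cumulative-power rule with interpolation", {
  psd <- list(freq = seq(0, 50, by = 0.25), power = rep(0, 201))
  flat <- psd; flat$power[flat$freq >= 0.5 & flat$freq <= 35] <- 1
  expect_equal(as.numeric(sef90(flat)), 0.5 + 0.9 * 34.5, tolerance = 0.25)

  single <- psd; single$power[single$freq == 10] <- 3
  expect_equal(as.numeric(sef90(single)), 10, tolerance = 0.25)

  split <- psd; split$power[split$freq == 5] <- 1; split$power[split$freq == 20] <- 1
  expect_equal(as.numeric(sef90(split)), 20, tolerance = 0.25)

  degen <- sef90(psd)
  expect_equal(as.numeric(degen), 0.5)
  expect_true(attr(degen, "degenerate"))
})

test_that("the 65-feature vector has the documented layout and symmetries", {
  set.seed(21)
  ep <- matrix(rnorm(8 * 3000, sd = 20), 8)
  fv <- extract_features(ep, 100)
  expect_length(fv, 65)
  expect_identical(names(fv), feature_names())
  expect_error(extract_features(ep[1:7, ], 100), "8 channels")

  zero <- extract_features(matrix(0, 8, 3000), 100)
  expect_equal(unname(zero[1:64]), rep(0, 64))
  expect_equal(unname(zero[65]), 0.5)

  same <- matrix(rep(ep[1, ], 8), 8, byrow = TRUE)
  fs <- extract_features(same, 100)
  blocks <- matrix(fs[1:64], nrow = 8, byrow = TRUE)
  for (ch in 2:8) expect_equal(blocks[ch, ], blocks[1, ])

  # permutation equivariance of the per-channel blocks
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)
  fp <- extract_features(ep[perm, ], 100)
  bl <- matrix(fv[1:64], nrow = 8, byrow = TRUE)
  blp <- matrix(fp[1:64], nrow = 8, byrow = TRUE)
  expect_equal(blp, bl[perm, ], ignore_attr = TRUE)
  expect_equal(fp[65], fv[65])
})

test_that("amplitude scaling moves only the amplitude features", {
  set.seed(22)
  ep <- matrix(rnorm(8 * 3000, sd = 10), 8)
  f1 <- extract_features(ep, 100)
  f3 <- extract_features(3 * ep, 100)
  sel_amp <- grepl("\\.(mean|sd|rms)$", names(f1))
  expect_equal(unname(f3[sel_amp]), unname(3 * f1[sel_amp]), tolerance = 1e-9)
  expect_equal(f3[!sel_amp], f1[!sel_amp], tolerance = 1e-9)
})
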