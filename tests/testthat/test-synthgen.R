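test_that("Markov hypnograms honor the transition matrix", {
  set.seed(81)
  absorbing <- diag(3)
  h <- simulate_hypnogram(50, absorbing, initial_stage = 0)
  expect_true(all(h$labels == 0))

  uniform <- matrix(1 / 3, 3, 3)
  set.seed(82)
  hu <- simulate_hypnogram(30000, uniform)
  freqs <- tabulate(hu$labels + 1, 3) / 30000
  expect_true(all(abs(freqs - 1 / 3) < 0.02))

  set.seed(83); a <- simulate_hypnogram(200)
  set.seed(83); b <- simulate_hypnogram(200)
  expect_identical(a$labels, b$labels)

  expect_error(simulate_hypnogram(10, matrix(1, 3, 3)), "stochastic")
})

test_that("long-run stage frequencies approach the chain's stationary law", {
  P <- rbd_transition_matrix()
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  set.seed(84)
  h <- simulate_hypnogram(40000, P)
  freqs <- tabulate(h$labels + 1, 3) / 40000
  expect_true(all(abs(freqs - stat) < 0.03))
})

test_that("stage-conditioned epochs carry the intended spectral signatures", {
  cfg <- sim_config()
  set.seed(85); nrem <- simulate_epoch(1, cfg)
  set.seed(85); wake <- simulate_epoch(0, cfg)
  expect_equal(dim(nrem), c(8, 3000))

  rel <- function(ep) {
    t(vapply(1:8, function(ch)
      relative_band_powers(welch_psd(ep[ch, ], 100)), numeric(5)))
  }
  rn <- rel(nrem); rw <- rel(wake)
  expect_gt(mean(rn[, 1]), mean(rw[, 1]))          # NREM is delta-dominant
  # wake alpha is occipitally weighted: O1/O2 (rows 5,6) beat Fp1/Fp2 (1,2)
  expect_gt(mean(rw[5:6, 3]), mean(rw[1:2, 3]))

  expect_error(simulate_epoch(4, cfg), "unknown stage")
})

test_that("REM contamination raises low-gamma power monotonically", {
  lowgamma <- function(prob, seed) {
    cfg <- sim_config(rem_contamination_prob = prob)
    set.seed(seed)
    mean(replicate(12, {
      ep <- simulate_epoch(2, cfg)
      mean(vapply(1:8, function(ch)
        relative_band_powers(welch_psd(ep[ch, ], 100))[["rel_lowgamma"]],
        numeric(1)))
    }))
  }
  expect_gt(lowgamma(1.0, 86), lowgamma(0, 86))
})

test_that("cohorts are byte-identical reruns of the master seed", {
  cfg <- sim_config(n_subjects = 2, epochs_per_night = 6, seed = 87)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects[[1]]$recording$signals,
                   b$subjects[[1]]$recording$signals)
  expect_identical(a$subjects[[2]]$hypnogram$labels,
                   b$subjects[[2]]$hypnogram$labels)
  expect_identical(a$scales, b$scales)
  expect_equal(length(a$subjects), 2)
  expect_equal(ncol(a$subjects[[1]]$recording$signals), 6 * 3000)
})

test_that("planted scale effects behave as configured", {
  set.seed(88)
  rem <- simulate_rem_pcts(60)
  flat <- simulate_scales(rem, effects = list(
    s = list(intercept = 10, slope = 0, sd = 0, lo = 0, hi = 21)))
  expect_equal(unique(flat$s), 10)

  strong <- simulate_scales(rem, effects = list(
    s = list(intercept = 40, slope = -0.8, sd = 0, lo = 0, hi = 60)))
  expect_lt(spearman_rank(rem, strong$s)$rho, -0.95)
})

test_that("the default PSQI effect yields a population Spearman near -0.5", {
  set.seed(90)
  rhos <- replicate(300, {
    rem <- simulate_rem_pcts(44)
    spearman_rank(rem, simulate_scales(rem)$psqi)$rho
  })
  expect_lt(abs(mean(rhos) - (-0.5)), 0.05)
})

test_that("default features keep the three stages linearly separable", {
  ds <- small_cohort_dataset()$ds
  keep <- ds$usable
  set.seed(89)
  idx <- which(keep)
  tr <- sample(idx, round(0.6 * length(idx)))
  te <- setdiff(idx, tr)
  # relative band powers sum to one, so LDA warns about collinearity; harmless
  fit <- suppressWarnings(MASS::lda(ds$feat[tr, ], grouping = ds$y[tr]))
  acc <- mean(predict(fit, ds$feat[te, ])$class == ds$y[te])
  expect_gt(acc, 0.9)
})
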