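test_that("epoch metrics match a hand-tallied confusion matrix", {
  m <- epoch_metrics(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0))
  expect_equal(m$table$precision, c(0.5, 2 / 3, 1.0), tolerance = 1e-9)
  expect_equal(m$table$recall, c(0.5, 1.0, 0.5), tolerance = 1e-9)
  expect_equal(sum(m$confusion), 6)
  expect_equal(rowSums(m$confusion), m$table$support, ignore_attr = TRUE)

  perfect <- epoch_metrics(c(0, 1, 2, 1), c(0, 1, 2, 1))
  expect_equal(perfect$table$f1, rep(1, 3))
  expect_equal(perfect$accuracy, 1)

  all_one <- epoch_metrics(c(0, 1, 2), c(1, 1, 1))
  expect_equal(all_one$table$recall, c(0, 1, 0))
  expect_true(all_one$table$zero_denominator[1])
  expect_error(epoch_metrics(0:1, 0:2), "equal length")
})

test_that("epoch metrics agree with the brute-force tally on random cases", {
  set.seed(61)
  for (i in 1:150) {
    n <- sample(5:60, 1)
    ref <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    m <- epoch_metrics(ref, pred)
    o <- oracle_epoch_metrics(ref, pred)
    expect_equal(unname(m$confusion), o$confusion, ignore_attr = TRUE)
    expect_equal(m$table$precision, o$precision, tolerance = 1e-9)
    expect_equal(m$table$recall, o$recall, tolerance = 1e-9)
    # accuracy = trace / total; micro precision = recall = accuracy
    expect_equal(m$accuracy, sum(diag(o$confusion)) / n, tolerance = 1e-12)
  }
})

test_that("the class-balanced subset draws exactly per_class epochs per class", {
  set.seed(62)
  pool <- data.frame(reference = sample(0:2, 3000, replace = TRUE,
                                        prob = c(0.3, 0.5, 0.2)))
  pool$predicted <- ifelse(runif(3000) < 0.8, pool$reference,
                           sample(0:2, 3000, replace = TRUE))
  sub <- balanced_subset(pool, per_class = 463, seed = 9)
  expect_equal(nrow(sub), 1389)
  expect_equal(unname(table(sub$reference)), rep(463L, 3), ignore_attr = TRUE)
  # pairs preserved: the subset is literally a row subset of the pool
  expect_true(all(rownames(sub) %in% rownames(pool)))
  expect_identical(sub$predicted,
                   pool[rownames(sub), "predicted"])
  # reproducible under the same seed
  expect_identical(balanced_subset(pool, 463, seed = 9), sub)

  expect_equal(nrow(balanced_subset(pool, per_class = 1, seed = 1)), 3)
  tiny <- data.frame(reference = c(0, 0, 0, 1, 1, 1, 2, 2), predicted = 0)
  expect_error(balanced_subset(tiny, per_class = 3), "REM")
})

test_that("night summaries express REM and NREM relative to TST", {
  h <- hypnogram(c(rep(0, 75), rep(1, 100), rep(2, 25)))
  ns <- night_summary(h)
  expect_equal(ns$tst_min, 62.5)
  expect_equal(ns$rem_pct, 20)
  expect_equal(ns$nrem_pct, 80)
  expect_false(ns$undefined_pct)
  expect_equal(ns$rem_pct + ns$nrem_pct, 100, tolerance = 1e-9)

  all_rem <- night_summary(hypnogram(rep(2, 10)))
  expect_equal(all_rem$rem_pct, 100)
  expect_equal(all_rem$nrem_pct, 0)

  awake <- night_summary(hypnogram(rep(0, 10)))
  expect_equal(awake$tst_min, 0)
  expect_true(awake$undefined_pct)
})

test_that("Bland-Altman statistics match hand computation and mirror for NREM", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loa_low, same$loa_high, same$mae), rep(0, 4))

  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$bias, -4 / 3, tolerance = 1e-4)
  expect_equal(ba$sd_diff, 2.0817, tolerance = 1e-4)
  expect_equal(ba$loa_low, -5.4135, tolerance = 1e-3)
  expect_equal(ba$loa_high, 2.7469, tolerance = 1e-3)
  expect_equal(ba$mae, 2.0)
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  expect_gte(ba$mae, abs(ba$bias))

  # NREM% = 100 - REM% makes the NREM report the exact sign-mirror
  set.seed(63)
  rem_auto <- runif(12, 5, 30); rem_man <- rem_auto + rnorm(12)
  r <- bland_altman(rem_auto, rem_man)
  n <- bland_altman(100 - rem_auto, 100 - rem_man)
  expect_equal(n$bias, -r$bias)
  expect_equal(n$loa_low, -r$loa_high)
  expect_equal(n$loa_high, -r$loa_low)
  expect_equal(n$mae, r$mae)

  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("ICC(A,1) matches the two-way ANOVA oracle and penalizes offsets", {
  set.seed(64)
  x <- rnorm(10, 50, 10)
  perfect <- icc_a1(x, x)
  expect_equal(perfect$icc, 1, tolerance = 1e-9)

  offset <- icc_a1(x + 5, x)
  expect_lt(offset$icc, 1)
  expect_gt(offset$icc, 0)   # well-spread subjects keep it positive

  for (i in 1:60) {
    a <- rnorm(8, 20, 6)
    b <- a + rnorm(8, 0.5, 2)
    expect_equal(icc_a1(a, b)$icc, oracle_icc_a1(a, b), tolerance = 1e-9)
  }

  ic <- icc_a1(x + rnorm(10), x)
  expect_true(ic$ci_low <= ic$icc && ic$icc <= ic$ci_high)

  flat <- icc_a1(rep(3, 6), rep(3, 6))
  expect_true(flat$degenerate)
  expect_error(icc_a1(1:3, 1:3), "at least 5")
})

test_that("independent noise gives an ICC near zero on average", {
  set.seed(65)
  mean_icc <- mean(replicate(60, icc_a1(rnorm(100), rnorm(100))$icc))
  expect_lt(abs(mean_icc), 0.1)
})
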