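test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_rank(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rank(1:8, -(1:8)^3)$rho, -1)
  # rank-Pearson by hand: sum of rank-deviation products 8 over sd product 10
  expect_equal(spearman_rank(1:5, c(2, 1, 4, 3, 5))$rho, 0.8, tolerance = 1e-9)
  # invariance under strictly monotone transforms
  set.seed(71)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_rank(x, y)$rho
  expect_equal(spearman_rank(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_rank(x, 3 * y + 7)$rho, base, tolerance = 1e-12)

  cst <- spearman_rank(rep(1, 6), rnorm(6))
  expect_true(cst$undefined)
  expect_error(spearman_rank(1:3, 1:3), "at least 4")
})

test_that("Spearman agrees with the midrank-Pearson oracle, ties included", {
  set.seed(72)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x * sample(c(-1, 1), 1) + rnorm(n, sd = 2)
    expect_equal(spearman_rank(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-9)
  }
  # t-approximation p agrees with the closed form
  sp <- spearman_rank(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  tstat <- sp$rho * sqrt((sp$n - 2) / (1 - sp$rho^2))
  expect_equal(sp$p, 2 * pt(-abs(tstat), sp$n - 2), tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up enumeration", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  set.seed(73)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15 & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("standardized regression recovers planted effects", {
  set.seed(74)
  x <- rnorm(50)
  # exact linear relation: after z-scoring both sides the slope is 1
  # (lm warns about the perfect fit; that is the point of the case)
  exact <- suppressWarnings(standardized_ols(2 * scale(x)[, 1], x))
  expect_equal(exact$beta, 1, tolerance = 1e-9)
  expect_equal(exact$ci_high - exact$ci_low, 0, tolerance = 1e-7)

  betas <- replicate(120, {
    xx <- rnorm(44)
    yy <- -0.5 * scale(xx)[, 1] + rnorm(44)
    standardized_ols(yy, xx)$beta[1]
  })
  expect_lt(abs(mean(betas) - (-0.5)), 0.1)

  # lone standardized predictor: beta equals the Pearson correlation
  y2 <- rnorm(50) + 0.4 * x
  expect_equal(standardized_ols(y2, x)$beta[1], cor(x, y2), tolerance = 1e-9)

  cov <- data.frame(age = rnorm(50, 60, 8), dup = x)
  expect_error(standardized_ols(y2, x, cov), "collinear")
})

test_that("regression coefficients agree with the normal-equation oracle", {
  set.seed(75)
  for (i in 1:80) {
    n <- 40
    X <- cbind(rnorm(n), rnorm(n), rbinom(n, 1, 0.5))
    y <- X %*% c(0.5, -0.3, 0.8) + rnorm(n)
    res <- standardized_ols(y[, 1], X[, 1],
                            data.frame(age = X[, 2], sex = X[, 3]))
    zs <- function(v) (v - mean(v)) / sd(v)
    o <- oracle_ols_beta(zs(y[, 1]), cbind(zs(X[, 1]), zs(X[, 2]), X[, 3]))
    expect_equal(res$beta, o, tolerance = 1e-9)
  }
})

test_that("the association suite ties the pieces together", {
  set.seed(76)
  rem <- simulate_rem_pcts(44)
  scales <- simulate_scales(rem)
  rem_df <- data.frame(subject_id = scales$subject_id, rem_pct = rem)
  rep <- association_suite(rem_df, scales[, c("subject_id", "psqi", "ess", "rbdsq")],
                           scales[, c("subject_id", "age", "sex", "bmi", "medication")])
  expect_equal(rep$family_size, 3)
  expect_equal(nrow(rep$correlations), 3)
  expect_true(all(rep$correlations$q >= rep$correlations$p - 1e-15))
  expect_lt(rep$correlations$rho[rep$correlations$pair == "rem_pct~psqi"], 0)
  # regression table includes an adjusted REM% term for each scale
  expect_equal(sum(rep$regressions$term == "rem_pct"), 3)

  bad <- rem_df; bad$subject_id[1] <- "ghost"
  expect_error(association_suite(bad, scales), "ghost")
})
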