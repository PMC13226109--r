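# Independent brute-force oracles used to cross-check the package's
# statistics. Each reimplements the defining formula from first principles
# (explicit midranks, explicit DFT sums, explicit ANOVA decomposition)
# without touching the code path under test.

# midranks computed from scratch (sort + tie averaging), then the raw
# Pearson covariance formula on the ranks
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
      r[o[i:j]] <- mean(i:j)
      i <- j + 1L
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# literal step-up definition: q_(i) = min_{j >= i} p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(p[o][i:m] * m / (i:m), 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# ICC(A,1) point estimate from a long-format two-way ANOVA fitted by aov()
oracle_icc_a1 <- function(auto, manual) {
  n <- length(auto)
  d <- data.frame(y = c(auto, manual),
                  subj = factor(rep(seq_len(n), 2L)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1L]][, "Mean Sq"]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Welch band power recomputed with explicit O(n^2) DFT sums per segment
oracle_welch_band_power <- function(x, rate, lo, hi, closed_upper = FALSE,
                                    seg_seconds = 4) {
  m <- round(seg_seconds * rate)
  step <- m %/% 2L
  nseg <- (length(x) - m) %/% step + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / m))
  freqs <- (0:(m %/% 2L)) * rate / m
  acc <- numeric(m %/% 2L + 1L)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * step + 1L):((s - 1L) * step + m)] * w
    for (ki in 0:(m %/% 2L)) {
      re <- sum(seg * cos(-2 * pi * ki * (0:(m - 1)) / m))
      im <- sum(seg * sin(-2 * pi * ki * (0:(m - 1)) / m))
      acc[ki + 1L] <- acc[ki + 1L] + (re^2 + im^2)
    }
  }
  p <- acc / nseg / (rate * sum(w^2))
  p[-1L] <- 2 * p[-1L]
  if (m %% 2L == 0L) p[m %/% 2L + 1L] <- p[m %/% 2L + 1L] / 2
  df <- rate / m
  sel <- freqs >= lo & (if (closed_upper) freqs <= hi else freqs < hi)
  sum(p[sel]) * df
}

# per-class precision/recall tallied with explicit double loops
oracle_epoch_metrics <- function(ref, pred) {
  conf <- matrix(0, 3, 3)
  for (i in seq_along(ref)) conf[ref[i] + 1L, pred[i] + 1L] <-
      conf[ref[i] + 1L, pred[i] + 1L] + 1L
  prec <- rec <- numeric(3)
  for (c in 1:3) {
    prec[c] <- if (sum(conf[, c]) > 0) conf[c, c] / sum(conf[, c]) else 0
    rec[c] <- if (sum(conf[c, ]) > 0) conf[c, c] / sum(conf[c, ]) else 0
  }
  list(confusion = conf, precision = prec, recall = rec)
}

# least squares via the normal equations, no lm()
oracle_ols_beta <- function(y, X) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))[-1L]
}
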