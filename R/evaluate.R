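#' Epoch-level classification metrics
#'
#' Per-class precision, recall and F1 plus the 3 x 3 confusion matrix
#' (rows = reference, columns = predicted). A zero denominator yields 0
#' with a flag rather than NaN.
#'
#' @param reference,predicted Equal-length integer label vectors in
#'   `{0, 1, 2}`.
#' @return Object of class `epoch_metrics`: `confusion`, `table` (data
#'   frame with stage, precision, recall, f1, support, flags), `accuracy`.
#' @export
epoch_metrics <- function(reference, predicted) {
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  if (any(!(c(reference, predicted) %in% 0:2)))
    stop("labels must lie in {0, 1, 2}")
  lev <- factor(0:2, levels = 0:2)
  confusion <- table(reference = factor(reference, levels = 0:2),
                     predicted = factor(predicted, levels = 0:2))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(reference = .stage_levels,
                              predicted = .stage_levels)
  prec <- rec <- f1 <- numeric(3)
  flagged <- logical(3)
  for (i in 1:3) {
    tp <- confusion[i, i]
    colsum <- sum(confusion[, i]); rowsum <- sum(confusion[i, ])
    if (colsum == 0) { prec[i] <- 0; flagged[i] <- TRUE } else prec[i] <- tp / colsum
    if (rowsum == 0) { rec[i] <- 0; flagged[i] <- TRUE } else rec[i] <- tp / rowsum
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  structure(list(confusion = confusion,
                 table = data.frame(stage = .stage_levels, precision = prec,
                                    recall = rec, f1 = f1,
                                    support = rowSums(confusion),
                                    zero_denominator = flagged),
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 macro_f1 = mean(f1)),
            class = "epoch_metrics")
}

#' @export
print.epoch_metrics <- function(x, ...) {
  cat(sprintf("Epoch-level metrics (n = %d, accuracy %.3f, macro-F1 %.3f)\n",
              sum(x$confusion), x$accuracy, x$macro_f1))
  print(x$table[, c("stage", "precision", "recall", "f1", "support")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Class-balanced subset of pooled predictions
#'
#' Draws exactly `per_class` epochs per reference class, uniformly without
#' replacement and seeded, preserving each epoch's (reference, predicted)
#' pair. Used to display stage-wise metrics without majority-class
#' dominance; with the conventional 463 per class the subset has 1389
#' epochs.
#'
#' @param pooled Data frame with at least `reference` and `predicted`.
#' @param per_class Epochs to draw per reference class.
#' @param seed RNG seed.
#' @return Row-subset of `pooled`.
#' @export
balanced_subset <- function(pooled, per_class = 463, seed = 1) {
  stopifnot(is.data.frame(pooled), all(c("reference", "predicted") %in% names(pooled)))
  counts <- vapply(0:2, function(c) sum(pooled$reference == c), integer(1))
  short <- which(counts < per_class)
  if (length(short))
    stop("not enough pooled epochs for class ",
         paste(.stage_levels[short], collapse = ", "),
         " (need ", per_class, ", have ", paste(counts[short], collapse = ", "), ")")
  set.seed(seed)
  take <- unlist(lapply(0:2, function(c)
    sample(which(pooled$reference == c), per_class)))
  pooled[sort(take), , drop = FALSE]
}

#' Whole-night stage summary
#'
#' Total sleep time counts NREM and REM epochs at 0.5 min each; REM% and
#' NREM% are expressed relative to TST (not total recording time), so the
#' two always sum to 100 when any sleep is present. A night with no sleep
#' is returned with TST 0 and the percentage fields flagged undefined
#' rather than silently NaN.
#'
#' @param h A [hypnogram()].
#' @return List of class `night_summary`: `subject_id`, `tst_min`,
#'   `rem_pct`, `nrem_pct`, `undefined_pct` flag.
#' @export
night_summary <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  n_nrem <- sum(h$labels == 1L)
  n_rem <- sum(h$labels == 2L)
  tst <- 0.5 * (n_nrem + n_rem)
  if (tst > 0) {
    rem_pct <- 100 * n_rem / (n_nrem + n_rem)
    nrem_pct <- 100 - rem_pct
    undef <- FALSE
  } else {
    rem_pct <- NA_real_; nrem_pct <- NA_real_; undef <- TRUE
  }
  structure(list(subject_id = h$subject_id, tst_min = tst,
                 rem_pct = rem_pct, nrem_pct = nrem_pct,
                 undefined_pct = undef),
            class = "night_summary")
}

#' @export
print.night_summary <- function(x, ...) {
  if (x$undefined_pct)
    cat(sprintf("<night_summary> '%s': TST 0 min (no sleep; stage percentages undefined)\n",
                x$subject_id))
  else
    cat(sprintf("<night_summary> '%s': TST %.1f min, REM %.1f%%, NREM %.1f%% of TST\n",
                x$subject_id, x$tst_min, x$rem_pct, x$nrem_pct))
  invisible(x)
}

#' Bland-Altman agreement between automated and manual values
#'
#' Differences are automated minus manual. Bias is their mean, the 95%
#' limits of agreement are bias +/- 1.96 sample SD (n-1 denominator), and
#' MAE is the mean absolute difference.
#'
#' @param auto,manual Paired per-subject values, length >= 3.
#' @return List of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `mae`, `sd_diff`, `n`, `mean_values`, `differences`.
#' @export
bland_altman <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("paired vectors required")
  if (length(auto) < 3) stop("need at least 3 pairs")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, mae = mean(abs(d)),
                 sd_diff = s, n = length(d),
                 mean_values = (auto + manual) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, 95%% LoA [%.3f, %.3f], MAE %.3f\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$mae))
  invisible(x)
}

#' ICC(A,1): two-way model, absolute agreement, single measurement
#'
#' Point estimate from the two-way ANOVA mean squares (rows = subjects,
#' columns = the two raters) and the F-based 95% confidence interval of
#' McGraw & Wong. Absolute agreement penalizes a constant offset between
#' raters, unlike consistency forms.
#'
#' @param auto,manual Paired per-subject values, n >= 5.
#' @param conf Confidence level (0.95).
#' @return List of class `icc`: `icc`, `ci_low`, `ci_high`, `degenerate`
#'   flag (zero between-subject variance), mean squares.
#' @export
icc_a1 <- function(auto, manual, conf = 0.95) {
  if (length(auto) != length(manual)) stop("paired vectors required")
  n <- length(auto)
  if (n < 5) stop("need at least 5 subjects")
  k <- 2
  Y <- cbind(auto, manual)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- msr <= .Machine$double.eps * max(1, abs(grand))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom > 0) (msr - mse) / denom else NA_real_
  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 1 - conf
  if (!degenerate && is.finite(icc) && mse > 0) {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_lo <- stats::qf(1 - alpha / 2, n - 1, v)
    f_hi <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_lo * mse) /
      (f_lo * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_hi * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_hi * msr)
  } else {
    ci_low <- NA_real_; ci_high <- NA_real_
  }
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 degenerate = degenerate, msr = msr, msc = msc, mse = mse,
                 n = n),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  if (x$degenerate)
    cat("ICC(A,1): degenerate (no between-subject variance)\n")
  else
    cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f to %.3f), n = %d\n",
                x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Night-level agreement report for REM% and NREM%
#'
#' Convenience wrapper combining Bland-Altman, MAE and ICC(A,1) for both
#' stage proportions. Because NREM% = 100 - REM%, the NREM report is the
#' exact sign-mirror of the REM report.
#'
#' @param auto,manual Data frames with `subject_id`, `rem_pct`, `nrem_pct`.
#' @return List of class `agreement_report` with elements `rem` and `nrem`
#'   (each `ba` + `icc`) and the matched subject ids.
#' @export
agreement_report <- function(auto, manual) {
  if (!setequal(auto$subject_id, manual$subject_id))
    stop("subject id mismatch: ",
         paste(union(setdiff(auto$subject_id, manual$subject_id),
                     setdiff(manual$subject_id, auto$subject_id)),
               collapse = ", "))
  m <- manual[match(auto$subject_id, manual$subject_id), ]
  structure(list(
    rem = list(ba = bland_altman(auto$rem_pct, m$rem_pct),
               icc = icc_a1(auto$rem_pct, m$rem_pct)),
    nrem = list(ba = bland_altman(auto$nrem_pct, m$nrem_pct),
                icc = icc_a1(auto$nrem_pct, m$nrem_pct)),
    subjects = auto$subject_id), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("REM% of TST:  "); print(x$rem$ba); cat("  "); print(x$rem$icc)
  cat("NREM% of TST: "); print(x$nrem$ba); cat("  "); print(x$nrem$icc)
  invisible(x)
}
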