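#' Spearman rank correlation with t-approximation p value
#'
#' Midranks for ties, rho as the Pearson correlation of the ranks, and a
#' two-tailed p value from the t approximation with n - 2 degrees of
#' freedom. For n <= 10 an exact permutation p value is available.
#'
#' @param x,y Equal-length finite numeric vectors, n >= 4.
#' @param exact Use the exact permutation null (only for n <= 10).
#' @return List: `rho`, `p`, `n`, `undefined` flag (constant input).
#' @export
spearman_rank <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p only supported for n <= 10")
    perms <- .permutations(n)
    null_rho <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q values mapped back to the input order, capped at 1;
#' q >= p elementwise and a single p maps to itself.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return q values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Standardized multivariable linear regression
#'
#' Ordinary least squares of one clinical scale on one predictor plus
#' demographic covariates. The outcome and all continuous variables are
#' z-scored so the predictor coefficient is a standardized beta; binary
#' covariates (sex, medication) stay 0/1 and their coefficients are
#' reported unstandardized. 95% confidence intervals come from the t
#' distribution; perfect collinearity is an error naming the column.
#'
#' @param outcome Numeric outcome vector.
#' @param predictor Numeric predictor of interest.
#' @param covariates Optional data frame (e.g. `age`, `sex`, `bmi`,
#'   `medication`); columns with only values in `{0, 1}` are treated as
#'   binary.
#' @param predictor_name,outcome_name Labels for the report.
#' @param conf Confidence level.
#' @return Data frame of class `standardized_ols` with one row per model
#'   term: `term`, `beta`, `ci_low`, `ci_high`, `p`, `standardized`.
#' @export
standardized_ols <- function(outcome, predictor, covariates = NULL,
                             predictor_name = "predictor",
                             outcome_name = "outcome", conf = 0.95) {
  n <- length(outcome)
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("constant column cannot be standardized")
    (v - mean(v)) / s
  }
  df <- data.frame(.y = zs(outcome))
  df[[predictor_name]] <- zs(predictor)
  std <- stats::setNames(TRUE, predictor_name)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (all(v %in% c(0, 1))) { df[[nm]] <- v; std[nm] <- FALSE }
      else { df[[nm]] <- zs(v); std[nm] <- TRUE }
    }
  }
  p_terms <- ncol(df) - 1L
  if (n <= p_terms + 2L) stop("too few observations for ", p_terms, " predictors")
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: coefficient not estimable for ",
         paste(bad, collapse = ", "))
  }
  est <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf)
  keep <- rownames(est) != "(Intercept)"
  out <- data.frame(outcome = outcome_name, term = rownames(est)[keep],
                    beta = est[keep, 1L], ci_low = ci[keep, 1L],
                    ci_high = ci[keep, 2L], p = est[keep, 4L],
                    standardized = std[rownames(est)[keep]],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("standardized_ols", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Clinical association suite for automated REM%
#'
#' Stage-2 statistics: one Spearman correlation of REM% against every
#' clinical scale, Benjamini-Hochberg FDR across exactly that family of
#' tests, and one covariate-adjusted standardized regression per scale
#' (scale as outcome, REM% as predictor). Two-tailed, alpha = 0.05.
#'
#' @param rem_pct Data frame with `subject_id` and `rem_pct`.
#' @param scales Data frame with `subject_id` and one column per clinical
#'   scale (e.g. `psqi`, `ess`, `rbdsq`).
#' @param covariates Optional data frame with `subject_id` plus covariate
#'   columns (`age`, `sex`, `bmi`, `medication`).
#' @param alpha Significance level recorded in the report.
#' @return Object of class `association_report`: `correlations` (pair,
#'   rho, p, q), `regressions` (stacked [standardized_ols()] rows),
#'   `family_size`, `alpha`.
#' @export
association_suite <- function(rem_pct, scales, covariates = NULL,
                              alpha = 0.05) {
  if (!setequal(rem_pct$subject_id, scales$subject_id))
    stop("subject id mismatch between REM%% table and scales: ",
         paste(union(setdiff(rem_pct$subject_id, scales$subject_id),
                     setdiff(scales$subject_id, rem_pct$subject_id)),
               collapse = ", "))
  scales <- scales[match(rem_pct$subject_id, scales$subject_id), ]
  cov_df <- NULL
  if (!is.null(covariates)) {
    if (!setequal(rem_pct$subject_id, covariates$subject_id))
      stop("subject id mismatch in covariates table")
    cov_df <- covariates[match(rem_pct$subject_id, covariates$subject_id),
                         setdiff(names(covariates), "subject_id"),
                         drop = FALSE]
  }
  scale_names <- setdiff(names(scales), "subject_id")
  cors <- do.call(rbind, lapply(scale_names, function(nm) {
    sp <- spearman_rank(rem_pct$rem_pct, scales[[nm]])
    data.frame(pair = paste0("rem_pct~", nm), rho = sp$rho, p = sp$p,
               stringsAsFactors = FALSE)
  }))
  cors$q <- bh_fdr(cors$p)
  regs <- do.call(rbind, lapply(scale_names, function(nm)
    standardized_ols(scales[[nm]], rem_pct$rem_pct, cov_df,
                     predictor_name = "rem_pct", outcome_name = nm)))
  structure(list(correlations = cors, regressions = regs,
                 family_size = length(scale_names), alpha = alpha,
                 n = nrow(rem_pct)),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("Clinical associations of automated REM%% (n = %d, FDR family of %d tests, alpha = %.2f)\n",
              x$n, x$family_size, x$alpha))
  print(x$correlations, row.names = FALSE, digits = 3)
  cat("Adjusted standardized regressions (REM% term per scale):\n")
  rem_rows <- x$regressions[x$regressions$term == "rem_pct", ]
  print(rem_rows, row.names = FALSE, digits = 3)
  invisible(x)
}
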