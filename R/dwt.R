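# Periodized orthogonal discrete wavelet transform (Daubechies-4) and
# universal soft-threshold denoising. Decomposition requires the working
# length to be divisible by 2^level, so signals are symmetrically padded to
# the next multiple and truncated after reconstruction.

# db4 (D8) scaling filter; wavelet filter by quadrature mirror.
.db4_h <- c(0.230377813308855, 0.714846570552916, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997)
.db4_g <- rev(.db4_h) * c(1, -1, 1, -1, 1, -1, 1, -1)

# one analysis step: x (even length) -> list(approx, detail), periodic boundary
.dwt_step <- function(x) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(.db4_h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + .db4_h[k] * x[idx]
    d <- d + .db4_g[k] * x[idx]
  }
  list(a = a, d = d)
}

# one synthesis step (transpose of the analysis operator)
.idwt_step <- function(a, d) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(.db4_h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    x[idx] <- x[idx] + .db4_h[k] * a + .db4_g[k] * d
  }
  x
}

.dwt_decompose <- function(x, level) {
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- .dwt_step(a)
    details[[j]] <- s$d         # details[[1]] = finest scale
    a <- s$a
  }
  list(approx = a, details = details)
}

.dwt_reconstruct <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) a <- .idwt_step(a, dec$details[[j]])
  a
}

.soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

.dwt_denoise_vector <- function(x, level) {
  n0 <- length(x)
  block <- 2L^level
  pad <- (block - n0 %% block) %% block
  if (pad > 0) {
    # symmetric extension keeps the padded tail smooth
    tail_ref <- rev(x)[seq_len(min(pad, n0))]
    x <- c(x, rep_len(tail_ref, pad))
  }
  dec <- .dwt_decompose(x, level)
  # noise scale from the finest-detail coefficients (robust MAD estimate)
  sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, .soft_threshold, thr = thr)
  .dwt_reconstruct(dec)[seq_len(n0)]
}

#' Wavelet soft-threshold denoising of a recording
#'
#' Per-channel discrete wavelet decomposition (Daubechies-4, periodized),
#' soft-thresholding of all detail coefficients at the universal threshold
#' `sigma * sqrt(2 log N)` with `sigma = MAD(finest detail)/0.6745`, and
#' reconstruction. Suppresses transient broad-band noise while preserving
#' the oscillatory sleep EEG morphology; output length equals input length.
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [preprocess_config()]; uses `wavelet` and `dwt_level`.
#' @return The denoised `eeg_recording`.
#' @export
dwt_denoise <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!identical(cfg$wavelet, "db4"))
    stop("unknown wavelet '", cfg$wavelet, "': only 'db4' is implemented")
  level <- cfg$dwt_level
  if (ncol(rec$signals) < 2L^level)
    stop("signal shorter than 2^level = ", 2L^level, " samples")
  out <- rec$signals
  for (i in seq_len(nrow(out))) out[i, ] <- .dwt_denoise_vector(out[i, ], level)
  recording(out, rec$rate, rec$channel_names, rec$subject_id)
}
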