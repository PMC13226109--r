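#' Canonical EEG frequency bands
#'
#' Delta, theta, alpha, beta and low-gamma edges partitioning the 0.5-35 Hz
#' clinical band without overlap.
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "lowgamma"),
             low  = c(0.5, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 35),
             stringsAsFactors = FALSE)
}

.FEATURE_EPS <- 1e-12

#' Time-domain amplitude statistics of one epoch channel
#'
#' @param x Numeric vector of samples (length >= 2).
#' @return Named vector `(mean, sd, rms)`; `sd` uses the n-1 denominator.
#' @export
time_stats <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  c(mean = mean(x), sd = stats::sd(x), rms = sqrt(mean(x^2)))
}

#' Welch power spectral density of one epoch channel
#'
#' Hann-windowed segments of `seg_seconds` (default 4 s, giving 0.25 Hz
#' resolution — enough to resolve the 0.5 Hz delta edge) with 50% overlap,
#' averaged modified periodograms, one-sided density scaling.
#'
#' @param x Samples of one 30-s epoch channel (`length == 30 * rate`).
#' @param rate Sampling rate, Hz.
#' @param seg_seconds Segment length in seconds.
#' @return List with `freq` (Hz, 0..rate/2) and `power` (uV^2/Hz, >= 0).
#' @export
welch_psd <- function(x, rate, seg_seconds = 4) {
  n <- length(x)
  if (n != round(30 * rate))
    stop("expected a 30-s epoch of ", round(30 * rate), " samples, got ", n)
  m <- as.integer(round(seg_seconds * rate))
  step <- m %/% 2L
  nseg <- (n - m) %/% step + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / m))   # periodic Hann
  scale <- 1 / (rate * sum(w^2))
  starts <- (seq_len(nseg) - 1L) * step
  segs <- vapply(starts, function(s) x[(s + 1L):(s + m)] * w, numeric(m))
  spec <- Mod(stats::mvfft(segs))^2
  p <- rowMeans(spec)[1:(m %/% 2L + 1L)] * scale
  p[-1] <- 2 * p[-1]
  p[m %/% 2L + 1L] <- p[m %/% 2L + 1L] / 2
  list(freq = (0:(m %/% 2L)) * rate / m, power = p)
}

.band_power <- function(psd, low, high, closed_upper = FALSE) {
  df <- psd$freq[2L] - psd$freq[1L]
  sel <- psd$freq >= low & (if (closed_upper) psd$freq <= high else psd$freq < high)
  sum(psd$power[sel]) * df
}

#' Relative band powers from a PSD
#'
#' Each band integral divided by the total 0.5-35 Hz integral; the five
#' values sum to one whenever total in-band power exceeds the degeneracy
#' guard, and are all zero otherwise.
#'
#' @param psd Output of [welch_psd()].
#' @param bands Band table as from [eeg_bands()].
#' @return Named numeric vector of five relative powers in `[0, 1]`.
#' @export
relative_band_powers <- function(psd, bands = eeg_bands()) {
  k <- nrow(bands)
  abs_p <- vapply(seq_len(k), function(i)
    .band_power(psd, bands$low[i], bands$high[i], closed_upper = (i == k)),
    numeric(1))
  total <- sum(abs_p)
  out <- if (total > .FEATURE_EPS) abs_p / total else rep(0, k)
  names(out) <- paste0("rel_", bands$name)
  out
}

#' Spectral edge frequency (SEF90)
#'
#' The smallest frequency f in the 0.5-35 Hz band below which 90% of the
#' band-limited spectral power lies, with linear interpolation between PSD
#' bins. A degenerate (essentially zero-power) spectrum returns the lower
#' band edge with a `degenerate` attribute set.
#'
#' @param psd Output of [welch_psd()].
#' @param quantile Edge quantile (0.90).
#' @param band Two-element band limits, Hz.
#' @return SEF in Hz.
#' @export
sef90 <- function(psd, quantile = 0.90, band = c(0.5, 35)) {
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  f <- psd$freq[sel]; p <- psd$power[sel]
  total <- sum(p)
  if (total <= .FEATURE_EPS)
    return(structure(band[1], degenerate = TRUE))
  cum <- cumsum(p)
  target <- quantile * total
  i <- which(cum >= target)[1L]
  if (i == 1L) {
    lo_f <- if (sel[1L] > 1L) psd$freq[sel[1L] - 1L] else f[1L]
    lo_c <- 0
  } else {
    lo_f <- f[i - 1L]; lo_c <- cum[i - 1L]
  }
  structure(lo_f + (target - lo_c) / (cum[i] - lo_c) * (f[i] - lo_f),
            degenerate = FALSE)
}

#' Names of the 65 handcrafted features, in order
#'
#' Layout version 1: eight per-channel blocks of eight features
#' (`mean`, `sd`, `rms`, then the five relative band powers) over the
#' canonical montage, followed by one global feature, the channel-averaged
#' SEF90. Variance is omitted as redundant with the standard deviation.
#'
#' @param channels Channel labels (default canonical montage).
#' @return Character vector of length 65.
#' @export
feature_names <- function(channels = canonical_montage()) {
  per <- c("mean", "sd", "rms", paste0("rel_", eeg_bands()$name))
  c(as.vector(t(outer(channels, per, paste, sep = "."))), "sef90_mean")
}

#' Extract the 65-dimensional handcrafted feature vector of one epoch
#'
#' Per channel: mean, SD and RMS amplitude (uV) and the five relative Welch
#' band powers; globally: the channel-mean SEF90 (Hz). Relative powers make
#' the spectral features amplitude-invariant across recordings.
#'
#' @param epoch Numeric matrix `8 x (30 * rate)`, microvolts.
#' @param rate Sampling rate, Hz.
#' @return Named numeric vector of length 65.
#' @export
extract_features <- function(epoch, rate) {
  epoch <- as.matrix(epoch)
  if (nrow(epoch) != 8L)
    stop("expected 8 channels, got ", nrow(epoch))
  sefs <- numeric(8L)
  out <- numeric(0)
  for (ch in 1:8) {
    x <- epoch[ch, ]
    psd <- welch_psd(x, rate)
    sef <- sef90(psd)
    sefs[ch] <- as.numeric(sef)
    out <- c(out, time_stats(x), relative_band_powers(psd))
  }
  out <- c(out, mean(sefs))
  names(out) <- feature_names()
  out
}

#' Feature matrix for all epochs of an epoch array
#'
#' @param epochs An `epoch_array` at the model rate.
#' @return Numeric matrix `n_epochs x 65` with named columns.
#' @export
extract_feature_matrix <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  n <- n_epochs(epochs)
  out <- matrix(0, n, 65L, dimnames = list(NULL, feature_names()))
  for (e in seq_len(n))
    out[e, ] <- extract_features(epochs$data[e, , , drop = TRUE], epochs$rate)
  out
}
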