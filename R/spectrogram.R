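#' Spectrogram configuration
#'
#' STFT parameters for the 2D image stream: 128-sample Hann window with a
#' 32-sample hop at 100 Hz gives ~0.78 Hz by 0.32 s resolution, balancing
#' time and frequency detail for 0.5-35 Hz sleep EEG content.
#'
#' @param window STFT window length, samples.
#' @param hop Hop between frames, samples.
#' @param eps Floor inside the log compression `log10(power + eps)`.
#' @param band Frequency rows retained, Hz.
#' @param side Output grid side length (32).
#' @return List of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window = 128, hop = 32, eps = 1e-10,
                               band = c(0.5, 35), side = 32) {
  structure(list(window = window, hop = hop, eps = eps, band = band,
                 side = side), class = "spectrogram_config")
}

#' STFT log-power spectrogram of one epoch channel
#'
#' Magnitude-squared short-time Fourier transform with a periodic Hann
#' window, log-compressed as `log10(power + eps)`, frequency rows
#' restricted to the clinical band.
#'
#' @param x Samples of one 30-s epoch channel (`length == 30 * rate`).
#' @param rate Sampling rate, Hz.
#' @param cfg A [spectrogram_config()].
#' @return Matrix (frequency rows ascending x time frames) with `freq` and
#'   `time` attributes.
#' @export
stft_spectrogram <- function(x, rate, cfg = spectrogram_config()) {
  m <- cfg$window
  if (m > length(x)) stop("STFT window (", m, ") longer than the epoch")
  hop <- cfg$hop
  nfrm <- (length(x) - m) %/% hop + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / m))
  starts <- (seq_len(nfrm) - 1L) * hop
  frames <- vapply(starts, function(s) x[(s + 1L):(s + m)] * w, numeric(m))
  pow <- Mod(stats::mvfft(frames))^2
  freqs <- (0:(m %/% 2L)) * rate / m
  keep <- which(freqs >= cfg$band[1] & freqs <= cfg$band[2])
  out <- log10(pow[keep, , drop = FALSE] + cfg$eps)
  attr(out, "freq") <- freqs[keep]
  attr(out, "time") <- (starts + m / 2) / rate
  out
}

#' Bilinear resize of a matrix to a fixed grid
#'
#' Align-corners bilinear interpolation: a constant input stays constant,
#' outputs are bounded by the input range, and a matrix already at the
#' target size is returned unchanged.
#'
#' @param m Non-empty numeric matrix.
#' @param rows,cols Target dimensions.
#' @return `rows x cols` matrix.
#' @export
resize_bilinear <- function(m, rows = 32, cols = 32) {
  m <- as.matrix(m)
  if (!length(m)) stop("cannot resize an empty matrix")
  interp_weights <- function(n_in, n_out) {
    # sparse-as-dense interpolation operator (n_out x n_in)
    W <- matrix(0, n_out, n_in)
    if (n_in == 1L) { W[, 1L] <- 1; return(W) }
    pos <- if (n_out == 1L) (n_in - 1) / 2 else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    lo <- pmin(floor(pos), n_in - 2)
    frac <- pos - lo
    for (i in seq_len(n_out)) {
      W[i, lo[i] + 1L] <- 1 - frac[i]
      W[i, lo[i] + 2L] <- W[i, lo[i] + 2L] + frac[i]
    }
    W
  }
  Wr <- interp_weights(nrow(m), rows)
  Wc <- interp_weights(ncol(m), cols)
  Wr %*% m %*% t(Wc)
}

#' Build the 8 x 32 x 32 spectrogram tensor of one epoch
#'
#' Per channel: STFT log-power spectrogram, bilinear resize to the square
#' grid, then z-normalization over the grid (guarded for constant planes,
#' which map to all-zero). Channel order is preserved.
#'
#' @param epoch Numeric matrix `8 x (30 * rate)` at the model rate.
#' @param rate Sampling rate, Hz (100).
#' @param cfg A [spectrogram_config()].
#' @return Array `8 x side x side` with per-channel `norm_mean`/`norm_sd`
#'   attributes.
#' @export
spectrogram_tensor <- function(epoch, rate = 100, cfg = spectrogram_config()) {
  epoch <- as.matrix(epoch)
  if (nrow(epoch) != 8L) stop("expected 8 channels, got ", nrow(epoch))
  side <- cfg$side
  out <- array(0, dim = c(8L, side, side))
  mus <- sds <- numeric(8L)
  for (ch in 1:8) {
    g <- resize_bilinear(stft_spectrogram(epoch[ch, ], rate, cfg), side, side)
    mu <- mean(g); sd_ <- stats::sd(as.vector(g))
    mus[ch] <- mu; sds[ch] <- sd_
    out[ch, , ] <- if (sd_ > 1e-12) (g - mu) / sd_ else 0
  }
  attr(out, "norm_mean") <- mus
  attr(out, "norm_sd") <- sds
  out
}

#' Spectrogram tensors for all epochs of an epoch array
#'
#' @param epochs An `epoch_array` at the model rate.
#' @param cfg A [spectrogram_config()].
#' @return Array `n_epochs x 8 x side x side`.
#' @export
spectrogram_array <- function(epochs, cfg = spectrogram_config()) {
  stopifnot(inherits(epochs, "epoch_array"))
  n <- n_epochs(epochs)
  side <- cfg$side
  out <- array(0, dim = c(n, 8L, side, side))
  for (e in seq_len(n))
    out[e, , , ] <- spectrogram_tensor(epochs$data[e, , , drop = TRUE],
                                       epochs$rate, cfg)
  out
}
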