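#' Canonical eight-channel clinical EEG montage
#'
#' The eight routinely available PSG-derived EEG electrodes used throughout
#' the pipeline, in their canonical order: prefrontal (Fp1/Fp2), central
#' (C3/C4), occipital (O1/O2) and the two mastoid references (A1/A2).
#'
#' @return Character vector of eight channel labels.
#' @export
canonical_montage <- function() {
  c("Fp1", "Fp2", "C3", "C4", "O1", "O2", "A1", "A2")
}

#' Construct a multichannel EEG recording
#'
#' A recording is a channels-by-samples matrix of microvolt values plus a
#' sampling rate and ordered channel labels. All channels share one rate and
#' one length.
#'
#' @param signals Numeric matrix, `n_channels x n_samples`, microvolts.
#' @param rate Sampling frequency in Hz (> 0).
#' @param channel_names Character vector, one label per row of `signals`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signals, rate, channel_names, subject_id = "anonymous") {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("`signals` must be a numeric matrix")
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number")
  if (nrow(signals) != length(channel_names))
    stop("number of channels (", nrow(signals), ") does not match number of labels (",
         length(channel_names), ")")
  rownames(signals) <- channel_names
  structure(
    list(subject_id = subject_id, signals = signals, rate = rate,
         channel_names = as.character(channel_names)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signals), ncol(x$signals), x$rate,
              ncol(x$signals) / x$rate))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Select and reorder channels of a recording
#'
#' Extracts the wanted channels (by default the canonical eight-channel
#' montage) and returns them in the requested order. Matching is
#' case-insensitive by default, with an exact-name fallback; reference
#' suffixes such as `"C3-A2"` can optionally be stripped before matching.
#'
#' @param rec An `eeg_recording`.
#' @param wanted Ordered channel labels to keep; defaults to
#'   [canonical_montage()].
#' @param ignore_case Match labels case-insensitively (default `TRUE`).
#' @param strip_reference Strip a `"-REF"`-style suffix from recorded labels
#'   before matching (default `FALSE`).
#' @return An `eeg_recording` containing exactly `wanted`, in order.
#' @export
select_montage <- function(rec, wanted = canonical_montage(),
                           ignore_case = TRUE, strip_reference = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  have <- rec$channel_names
  have_key <- have
  if (strip_reference) have_key <- sub("-.*$", "", have_key)
  idx <- match(wanted, have_key)
  if (ignore_case) {
    miss <- is.na(idx)
    idx[miss] <- match(tolower(wanted[miss]), tolower(have_key))
  }
  if (anyNA(idx)) {
    stop("channel(s) not present in recording: ",
         paste(wanted[is.na(idx)], collapse = ", "))
  }
  recording(rec$signals[idx, , drop = FALSE], rec$rate,
            wanted, rec$subject_id)
}

#' Segment a recording into 30-second epochs
#'
#' Epoch boundaries are half-open, zero-based and aligned to the first
#' sample; a trailing partial window is discarded, matching standard 30-s
#' scoring practice. A recording shorter than one epoch yields an empty
#' array, not an error.
#'
#' @param rec An `eeg_recording` whose `rate * 30` is an integer.
#' @param epoch_seconds Epoch length in seconds (30, the scoring standard).
#' @return An object of class `epoch_array`: list with `data` (array
#'   `n_epochs x n_channels x samples_per_epoch`), `rate`, `subject_id`.
#' @export
epoch_signals <- function(rec, epoch_seconds = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- rec$rate * epoch_seconds
  if (abs(spe - round(spe)) > 1e-9)
    stop("rate * ", epoch_seconds, " must be an integer number of samples")
  spe <- as.integer(round(spe))
  n_ch <- nrow(rec$signals)
  n_ep <- ncol(rec$signals) %/% spe
  if (n_ep == 0L) {
    data <- array(numeric(0), dim = c(0L, n_ch, spe))
  } else {
    used <- rec$signals[, seq_len(n_ep * spe), drop = FALSE]
    # (ch, sample-within-epoch, epoch) -> (epoch, ch, sample)
    data <- aperm(array(used, dim = c(n_ch, spe, n_ep)), c(3L, 1L, 2L))
  }
  structure(list(data = data, rate = rec$rate, subject_id = rec$subject_id,
                 channel_names = rec$channel_names),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> subject '%s': %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$rate))
  invisible(x)
}

#' Number of epochs in an epoch array
#' @param x An `epoch_array`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_array"))
  dim(x$data)[1]
}
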