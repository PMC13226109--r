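#' Build the per-epoch three-stream dataset for a cohort
#'
#' Runs every recording through the fixed conditioning chain (band-pass,
#' wavelet denoising, resampling, epoching, artifact screening), then
#' extracts the three model inputs per usable 30-s epoch: the raw
#' 8 x 3000 waveform, the 8 x 32 x 32 spectrogram tensor and the 65-d
#' handcrafted vector, aligned with the reference hypnogram labels.
#'
#' @param cohort List of subjects, each a list with elements `recording`
#'   (an `eeg_recording`) and `hypnogram` (a [hypnogram()]), as produced by
#'   [simulate_cohort()].
#' @param cfg A [preprocess_config()].
#' @param spec_cfg A [spectrogram_config()].
#' @param denoise Apply wavelet denoising (default `TRUE`).
#' @return List of class `epoch_dataset`: `raw` (n x 8 x 3000), `spec`
#'   (n x 8 x 32 x 32), `feat` (n x 65), `y` (labels 0/1/2), `subject`,
#'   `epoch` (index within night), `usable` (artifact mask).
#' @export
build_epoch_dataset <- function(cohort, cfg = preprocess_config(),
                                spec_cfg = spectrogram_config(),
                                denoise = TRUE) {
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$subjects
  parts <- lapply(cohort, function(sub) {
    pp <- preprocess_recording(sub$recording, cfg, denoise = denoise)
    n_ep <- min(n_epochs(pp$epochs), length(sub$hypnogram$labels))
    if (n_ep == 0L) return(NULL)
    feat <- matrix(0, n_ep, 65L)
    spec <- array(0, dim = c(n_ep, 8L, spec_cfg$side, spec_cfg$side))
    for (e in seq_len(n_ep)) {
      ep <- pp$epochs$data[e, , , drop = TRUE]
      feat[e, ] <- extract_features(ep, cfg$model_rate)
      spec[e, , , ] <- spectrogram_tensor(ep, cfg$model_rate, spec_cfg)
    }
    list(raw = pp$epochs$data[seq_len(n_ep), , , drop = FALSE],
         spec = spec, feat = feat,
         y = sub$hypnogram$labels[seq_len(n_ep)],
         subject = rep(sub$recording$subject_id, n_ep),
         epoch = seq_len(n_ep),
         usable = pp$qc$usable[seq_len(n_ep)])
  })
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) stop("cohort produced no full epochs")
  ds <- list(raw = do.call(abind3, lapply(parts, `[[`, "raw")),
             spec = do.call(abind4, lapply(parts, `[[`, "spec")),
             feat = do.call(rbind, lapply(parts, `[[`, "feat")),
             y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
             subject = unlist(lapply(parts, `[[`, "subject"), use.names = FALSE),
             epoch = unlist(lapply(parts, `[[`, "epoch"), use.names = FALSE),
             usable = unlist(lapply(parts, `[[`, "usable"), use.names = FALSE))
  colnames(ds$feat) <- feature_names()
  structure(ds, class = "epoch_dataset")
}

# bind arrays along the first axis (epochs)
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  out <- array(0, dim = c(sum(vapply(xs, function(x) dim(x)[1L], integer(1))), d[2L], d[3L]))
  at <- 0L
  for (x in xs) { n <- dim(x)[1L]; out[at + seq_len(n), , ] <- x; at <- at + n }
  out
}

abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  out <- array(0, dim = c(sum(vapply(xs, function(x) dim(x)[1L], integer(1))), d[2L], d[3L], d[4L]))
  at <- 0L
  for (x in xs) { n <- dim(x)[1L]; out[at + seq_len(n), , , ] <- x; at <- at + n }
  out
}

#' Subset an epoch dataset by epoch index
#' @param ds An `epoch_dataset`.
#' @param idx Integer epoch indices to keep.
#' @return The subset `epoch_dataset`.
#' @export
dataset_subset <- function(ds, idx) {
  structure(list(raw = ds$raw[idx, , , drop = FALSE],
                 spec = ds$spec[idx, , , , drop = FALSE],
                 feat = ds$feat[idx, , drop = FALSE],
                 y = ds$y[idx], subject = ds$subject[idx],
                 epoch = ds$epoch[idx], usable = ds$usable[idx]),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf("<epoch_dataset> %d epochs from %d subjects (%d usable)\n",
              length(x$y), length(unique(x$subject)), sum(x$usable)))
  invisible(x)
}
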