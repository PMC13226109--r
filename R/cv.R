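#' Assign subjects to cross-validation folds
#'
#' Every epoch of a subject belongs to that subject's single fold, the
#' construction that prevents information leakage between development and
#' test data. Subjects are shuffled (seeded) and dealt round-robin.
#'
#' @param subjects Character vector of unique subject identifiers.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return Data frame (`subject`, `fold` in `0..k-1`).
#' @export
patient_folds <- function(subjects, k = 5, seed = 1) {
  subjects <- unique(as.character(subjects))
  if (length(subjects) < k)
    stop("need at least k = ", k, " subjects, got ", length(subjects))
  set.seed(seed)
  shuffled <- sample(subjects)
  data.frame(subject = shuffled,
             fold = rep_len(seq_len(k) - 1L, length(shuffled)),
             stringsAsFactors = FALSE)
}

#' Patient-wise k-fold cross-validation of the staging network
#'
#' For each fold, the held-out subjects' epochs are predicted by a model
#' fitted only on the remaining subjects (which internally reserve a
#' subject-wise validation split for early stopping and checkpoint
#' selection), so every epoch is predicted exactly once by a model that
#' never saw its subject in training, validation or selection. Held-out
#' predictions are pooled across folds. Artifact-flagged epochs are
#' excluded from development but still predicted.
#'
#' @param ds An [build_epoch_dataset()] result.
#' @param k Number of folds (5).
#' @param config A [msfnet_config()]; fold f trains with seed
#'   `config$seed + f`.
#' @param verbose Print per-fold progress.
#' @return Object of class `msfnet_cv`: `predictions` (pooled out-of-fold
#'   data frame keyed by subject and epoch index), `folds`, `metrics`
#'   (pooled [epoch_metrics()]), `history` per fold.
#' @export
msfnet_cv <- function(ds, k = 5, config = msfnet_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "epoch_dataset"))
  folds <- patient_folds(ds$subject, k, seed = config$seed)
  preds <- vector("list", k)
  hist <- vector("list", k)
  for (f in seq_len(k) - 1L) {
    test_subj <- folds$subject[folds$fold == f]
    dev_subj <- folds$subject[folds$fold != f]
    stopifnot(length(intersect(test_subj, dev_subj)) == 0L)  # leakage guard
    dev_idx <- which(ds$subject %in% dev_subj & ds$usable)
    test_idx <- which(ds$subject %in% test_subj)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    dev <- dataset_subset(ds, dev_idx)
    fit <- msfnet(list(raw = dev$raw, spec = dev$spec, feat = dev$feat),
                  dev$y, subjects = dev$subject, config = cfg_f,
                  verbose = verbose)
    stopifnot(length(intersect(test_subj, unique(dev$subject))) == 0L)
    test <- dataset_subset(ds, test_idx)
    pr <- predict(fit, list(raw = test$raw, spec = test$spec, feat = test$feat),
                  type = "prob")
    lab <- max.col(pr, ties.method = "first") - 1L
    preds[[f + 1L]] <- data.frame(subject = test$subject, epoch = test$epoch,
                                  reference = test$y, predicted = lab,
                                  p_wake = pr[, 1L], p_nrem = pr[, 2L],
                                  p_rem = pr[, 3L], usable = test$usable,
                                  fold = f, stringsAsFactors = FALSE)
    hist[[f + 1L]] <- fit$history
    if (verbose)
      message(sprintf("fold %d: test subjects %s, pooled so far %d epochs",
                      f, paste(test_subj, collapse = ","),
                      sum(vapply(preds, NROW, integer(1)))))
  }
  pooled <- do.call(rbind, preds)
  # partition property: every epoch of every subject predicted exactly once
  stopifnot(nrow(pooled) == length(ds$y),
            !anyDuplicated(pooled[, c("subject", "epoch")]))
  structure(list(predictions = pooled, folds = folds,
                 metrics = epoch_metrics(pooled$reference, pooled$predicted),
                 history = hist, k = k, config = config),
            class = "msfnet_cv")
}

#' @export
print.msfnet_cv <- function(x, ...) {
  cat(sprintf("Patient-wise %d-fold cross-validation: %d pooled out-of-fold epochs from %d subjects\n",
              x$k, nrow(x$predictions), nrow(x$folds)))
  print(x$metrics)
  invisible(x)
}

#' Stage a whole recording with a frozen model
#'
#' Applies the fixed conditioning chain and the frozen network to one
#' recording and returns automated 30-s labels. Artifact-flagged epochs
#' are still predicted, with a warning, matching the flag-and-keep policy
#' for inference.
#'
#' @param model A fitted [msfnet()].
#' @param rec An `eeg_recording` (at native rate; the chain resamples).
#' @param cfg A [preprocess_config()].
#' @param spec_cfg A [spectrogram_config()].
#' @param denoise Apply wavelet denoising.
#' @return List: `hypnogram` (automated labels), `probs` (n x 3), `qc`.
#' @export
predict_recording <- function(model, rec, cfg = preprocess_config(),
                              spec_cfg = spectrogram_config(), denoise = TRUE) {
  stopifnot(inherits(model, "msfnet"), inherits(rec, "eeg_recording"))
  ds <- build_epoch_dataset(
    list(list(recording = rec, hypnogram = hypnogram(rep(0L, max(
      1L, floor(ncol(rec$signals) / (rec$rate * 30)))), rec$subject_id))),
    cfg, spec_cfg, denoise = denoise)
  if (!length(ds$y)) stop("recording contains no full 30-s epoch")
  if (any(!ds$usable))
    warning(sum(!ds$usable), " epoch(s) failed artifact screening; ",
            "predictions for them are retained")
  pr <- predict(model, list(raw = ds$raw, spec = ds$spec, feat = ds$feat),
                type = "prob")
  lab <- max.col(pr, ties.method = "first") - 1L
  list(hypnogram = hypnogram(lab, rec$subject_id), probs = pr,
       qc = data.frame(epoch = ds$epoch, usable = ds$usable))
}
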