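#' Configuration of the multi-stream staging network
#'
#' Three parallel streams — a 1D CNN over the raw 8 x 3000 epoch waveform,
#' a 2D CNN over the 8 x 32 x 32 spectrogram tensor, and the 65-d
#' handcrafted vector — are each reduced to fixed embeddings (64 + 64 + 65),
#' concatenated to 193 dimensions, reweighted by a sigmoid-gated two-layer
#' MLP, and classified by three dense layers with dropout. The dimension
#' chain `embed_1d + embed_2d + handcrafted_dim == fused_dim` is asserted
#' here and again at model construction.
#'
#' @param conv1d,conv2d Per-stream block settings (channels, kernels,
#'   strides/pools). Three conv-norm-act-pool blocks per stream, global
#'   average pooling after the last.
#' @param embed_1d,embed_2d,handcrafted_dim,fused_dim Embedding dimensions.
#' @param gate_hidden Hidden width of the gating MLP.
#' @param classifier Widths of the two hidden dense layers.
#' @param dropout Dropout rates after each hidden dense layer.
#' @param n_classes Number of stages (3: Wake, NREM, REM).
#' @param lr Initial Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param lr_factor,lr_patience Reduce-on-plateau scheduler on validation
#'   loss: multiply `lr` by `lr_factor` after `lr_patience` stagnant epochs.
#' @param patience Early-stopping patience on validation macro-F1.
#' @param val_frac Fraction of development subjects held out as the
#'   internal validation set (at least one subject).
#' @param seed Seed driving initialization, shuffling, dropout and splits.
#' @param input_channels,input_length,spec_side Input tensor dimensions.
#' @return List of class `msfnet_config`.
#' @export
msfnet_config <- function(conv1d = list(channels = c(32, 64, 64),
                                        kernels = c(7, 5, 3),
                                        strides = c(4, 1, 1),
                                        pools = c(4, 4, 4)),
                          conv2d = list(channels = c(16, 32, 64),
                                        kernels = c(3, 3, 3),
                                        pools = c(2, 2, 2)),
                          embed_1d = 64, embed_2d = 64, handcrafted_dim = 65,
                          fused_dim = 193, gate_hidden = 96,
                          classifier = c(128, 64), dropout = c(0.5, 0.3),
                          n_classes = 3, lr = 0.001, batch_size = 64,
                          max_epochs = 30, lr_factor = 0.5, lr_patience = 3,
                          patience = 10, val_frac = 0.2, seed = 1,
                          input_channels = 8, input_length = 3000,
                          spec_side = 32) {
  if (utils::tail(conv1d$channels, 1) != embed_1d)
    stop("last 1D-stream channel count must equal embed_1d")
  if (utils::tail(conv2d$channels, 1) != embed_2d)
    stop("last 2D-stream channel count must equal embed_2d")
  if (fused_dim != embed_1d + embed_2d + handcrafted_dim)
    stop("dimension chain violated: fused_dim must equal embed_1d + embed_2d + handcrafted_dim (",
         embed_1d, " + ", embed_2d, " + ", handcrafted_dim, ")")
  structure(list(conv1d = conv1d, conv2d = conv2d, embed_1d = embed_1d,
                 embed_2d = embed_2d, handcrafted_dim = handcrafted_dim,
                 fused_dim = fused_dim, gate_hidden = gate_hidden,
                 classifier = classifier, dropout = dropout,
                 n_classes = n_classes, lr = lr, batch_size = batch_size,
                 max_epochs = max_epochs, lr_factor = lr_factor,
                 lr_patience = lr_patience, patience = patience,
                 val_frac = val_frac, seed = seed,
                 input_channels = input_channels,
                 input_length = input_length, spec_side = spec_side),
            class = "msfnet_config")
}

#' Inverse-frequency class weights for the cross-entropy loss
#'
#' `w_c = N_total / (n_classes * N_c)`: equal counts give unit weights, so
#' the weighted loss collapses to ordinary cross-entropy on balanced data.
#'
#' @param label_counts Positive integer counts per class, in label order.
#' @return Numeric weights, one per class.
#' @export
class_weights <- function(label_counts) {
  if (any(label_counts <= 0))
    stop("every class must be present in the development folds (zero count seen)")
  sum(label_counts) / (length(label_counts) * label_counts)
}

.stage_levels <- c("Wake", "NREM", "REM")

# natural layout -> engine layout for a subset of epochs
.make_batch <- function(x, idx, center, scale) {
  raw <- aperm(x$raw[idx, , , drop = FALSE], c(2L, 3L, 1L))
  raw <- .standardize_engine_raw(raw)
  sp <- aperm(x$spec[idx, , , , drop = FALSE], c(2L, 3L, 4L, 1L))
  dim(sp) <- c(dim(sp)[1L], dim(sp)[2L] * dim(sp)[3L], dim(sp)[4L])
  feat <- t(x$feat[idx, , drop = FALSE])
  feat <- (feat - center) / scale
  list(raw = raw, spec = sp, feat = feat)
}

.standardize_engine_raw <- function(raw) {
  # raw: (C, L, N); z-score each channel of each epoch over its 30 s
  d <- dim(raw)
  m <- apply(raw, c(1L, 3L), mean)                  # C x N
  s <- apply(raw, c(1L, 3L), stats::sd)
  s[!is.finite(s) | s < 1e-8] <- 1
  expand <- function(a) aperm(array(a, c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  (raw - expand(m)) / expand(s)
}

.check_inputs <- function(x, cfg) {
  d <- dim(x$raw)
  if (length(d) != 3L || d[2L] != cfg$input_channels || d[3L] != cfg$input_length)
    stop("raw stream must be n x ", cfg$input_channels, " x ", cfg$input_length)
  ds <- dim(x$spec)
  if (length(ds) != 4L || ds[2L] != cfg$input_channels ||
      ds[3L] != cfg$spec_side || ds[4L] != cfg$spec_side)
    stop("spectrogram stream must be n x ", cfg$input_channels, " x ",
         cfg$spec_side, " x ", cfg$spec_side)
  if (ncol(x$feat) != cfg$handcrafted_dim)
    stop("handcrafted stream must have ", cfg$handcrafted_dim, " columns")
  if (d[1L] != ds[1L] || d[1L] != nrow(x$feat))
    stop("stream sample counts disagree")
}

.macro_f1 <- function(ref, pred, n_classes = 3L) {
  f1 <- numeric(n_classes)
  for (c in seq_len(n_classes) - 1L) {
    tp <- sum(ref == c & pred == c)
    fp <- sum(ref != c & pred == c)
    fn <- sum(ref == c & pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1L] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1)
}

#' Fit the multi-stream gated-fusion staging network
#'
#' Trains the three-stream network with Adam on weighted cross-entropy,
#' using a subject-wise internal validation split for the
#' reduce-on-plateau learning-rate schedule, early stopping, and selection
#' of the checkpoint with the best validation macro-F1. Handcrafted
#' features are z-scored with statistics computed on the training epochs
#' only; raw waveforms are standardized per epoch and channel. All
#' randomness is driven by `config$seed`.
#'
#' @param x List with `raw` (n x 8 x 3000 array), `spec`
#'   (n x 8 x 32 x 32 array) and `feat` (n x 65 matrix).
#' @param y Integer stage labels in `{0, 1, 2}`.
#' @param subjects Subject identifier per epoch (enables the subject-wise
#'   validation split; `NULL` falls back to an epoch-wise split).
#' @param config A [msfnet_config()].
#' @param verbose Print one line per training epoch.
#' @return An object of class `msfnet` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @export
msfnet <- function(x, y, subjects = NULL, config = msfnet_config(),
                   verbose = FALSE) {
  .check_inputs(x, config)
  y <- as.integer(y)
  if (any(!(y %in% (seq_len(config$n_classes) - 1L))))
    stop("labels must lie in 0..", config$n_classes - 1L)
  n <- length(y)
  if (n != dim(x$raw)[1L]) stop("length(y) must match the number of epochs")
  set.seed(config$seed)

  # ---- internal validation split (subject-wise when possible) ----
  if (!is.null(subjects)) {
    subjects <- as.character(subjects)
    subj <- unique(subjects)
    n_val <- max(1L, round(config$val_frac * length(subj)))
    if (n_val >= length(subj))
      stop("not enough subjects for an internal validation split")
    val_subj <- sample(subj, n_val)
    val_idx <- which(subjects %in% val_subj)
  } else {
    val_subj <- character(0)
    n_val_ep <- max(1L, round(config$val_frac * n))
    val_idx <- sample.int(n, n_val_ep)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(val_idx)) stop("empty validation set")
  if (!length(tr_idx)) stop("empty training set")

  counts <- tabulate(y[tr_idx] + 1L, config$n_classes)
  w <- class_weights(counts)

  center <- colMeans(x$feat[tr_idx, , drop = FALSE])
  scale <- apply(x$feat[tr_idx, , drop = FALSE], 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1

  ini <- .nn_init(config)
  params <- ini$params; state <- ini$state
  opt <- .adam_init(params)
  lr <- config$lr

  val_batch_pred <- function(p, st) {
    preds <- integer(length(val_idx)); loss_n <- 0; loss_sum <- 0
    bs <- config$batch_size
    for (start in seq(1L, length(val_idx), by = bs)) {
      idx <- val_idx[start:min(start + bs - 1L, length(val_idx))]
      b <- .make_batch(x, idx, center, scale)
      fw <- .nn_forward(p, st, b, config, training = FALSE)
      preds[start:(start + length(idx) - 1L)] <-
        max.col(t(fw$probs), ties.method = "first") - 1L
      loss_sum <- loss_sum + .nn_loss(fw$probs, y[idx], w) * length(idx)
      loss_n <- loss_n + length(idx)
    }
    list(pred = preds, loss = loss_sum / loss_n)
  }

  best <- list(f1 = -Inf, params = params, state = state, epoch = 0L)
  history <- data.frame()
  stall_f1 <- 0L; stall_loss <- 0L; best_loss <- Inf
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    tr_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      b <- .make_batch(x, idx, center, scale)
      fw <- .nn_forward(params, state, b, config, training = TRUE)
      state <- fw$state
      loss <- .nn_loss(fw$probs, y[idx], w)
      dlog <- .nn_loss_grad(fw$probs, y[idx], w)
      grads <- .nn_backward(params, fw, dlog, config)
      stp <- .adam_step(params, grads, opt, lr)
      params <- stp$params; opt <- stp$opt
      tr_loss <- tr_loss + loss; nb <- nb + 1L
    }
    vl <- val_batch_pred(params, state)
    vf1 <- .macro_f1(y[val_idx], vl$pred, config$n_classes)
    history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                         train_loss = tr_loss / nb,
                                         val_loss = vl$loss, val_macro_f1 = vf1))
    if (verbose)
      message(sprintf("epoch %2d  lr %.2g  train %.4f  val %.4f  val-F1 %.3f",
                      ep, lr, tr_loss / nb, vl$loss, vf1))
    if (vf1 > best$f1 + 1e-9) {
      best <- list(f1 = vf1, params = params, state = state, epoch = ep)
      stall_f1 <- 0L
    } else stall_f1 <- stall_f1 + 1L
    if (vl$loss < best_loss - 1e-6) { best_loss <- vl$loss; stall_loss <- 0L }
    else {
      stall_loss <- stall_loss + 1L
      if (stall_loss >= config$lr_patience) { lr <- lr * config$lr_factor; stall_loss <- 0L }
    }
    if (stall_f1 >= config$patience) break
  }

  structure(list(params = best$params, state = best$state, config = config,
                 feat_center = center, feat_scale = scale,
                 class_weights = w, history = history,
                 best_val_f1 = best$f1, best_epoch = best$epoch,
                 val_subjects = val_subj, n_train = length(tr_idx),
                 n_val = length(val_idx), levels = .stage_levels),
            class = "msfnet")
}

#' @export
print.msfnet <- function(x, ...) {
  cat("Multi-stream gated-fusion sleep staging network\n")
  cat(sprintf("  streams: raw %dx%d -> %d | spectrogram %dx%dx%d -> %d | handcrafted %d\n",
              x$config$input_channels, x$config$input_length, x$config$embed_1d,
              x$config$input_channels, x$config$spec_side, x$config$spec_side,
              x$config$embed_2d, x$config$handcrafted_dim))
  cat(sprintf("  fused: %d gated features -> dense %s -> %d classes\n",
              x$config$fused_dim, paste(x$config$classifier, collapse = "/"),
              x$config$n_classes))
  cat(sprintf("  trained %d epochs on %d epochs (%d validation); best val macro-F1 %.3f (epoch %d)\n",
              nrow(x$history), x$n_train, x$n_val, x$best_val_f1, x$best_epoch))
  invisible(x)
}

#' @export
summary.msfnet <- function(object, ...) {
  print(object)
  cat("  class weights:", paste(sprintf("%.3f", object$class_weights), collapse = ", "), "\n")
  cat("  training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.msfnet <- function(object, ...) object$params

#' Predict stage probabilities or labels for new epochs
#'
#' Runs the frozen network in evaluation mode (deterministic). Ties in the
#' argmax are broken toward the lowest class index (Wake first).
#'
#' @param object A fitted [msfnet()].
#' @param newdata List with `raw`, `spec`, `feat` as in [msfnet()].
#' @param type `"class"` for integer labels 0/1/2, `"prob"` for the
#'   n x 3 probability matrix (rows sum to one).
#' @param ... Unused.
#' @return Integer labels or probability matrix.
#' @export
predict.msfnet <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  .check_inputs(newdata, cfg)
  n <- dim(newdata$raw)[1L]
  probs <- matrix(0, n, cfg$n_classes,
                  dimnames = list(NULL, .stage_levels[seq_len(cfg$n_classes)]))
  bs <- cfg$batch_size
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(start + bs - 1L, n)
    b <- .make_batch(newdata, idx, object$feat_center, object$feat_scale)
    fw <- .nn_forward(object$params, object$state, b, cfg, training = FALSE)
    probs[idx, ] <- t(fw$probs)
  }
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

#' Stream embeddings of a fitted network
#'
#' Exposes the per-stream encoders: the 64-d time-domain embedding of raw
#' epochs or the 64-d spectro-temporal embedding of spectrogram tensors,
#' both in evaluation mode.
#'
#' @param object A fitted [msfnet()].
#' @param input Raw array `n x 8 x 3000` (stream `"1d"`) or spectrogram
#'   array `n x 8 x 32 x 32` (stream `"2d"`).
#' @param stream Which encoder to run.
#' @return Matrix `n x 64`.
#' @export
msfnet_embed <- function(object, input, stream = c("1d", "2d")) {
  stream <- match.arg(stream)
  cfg <- object$config
  if (stream == "1d") {
    d <- dim(input)
    if (length(d) != 3L || d[2L] != cfg$input_channels || d[3L] != cfg$input_length)
      stop("raw input must be n x ", cfg$input_channels, " x ", cfg$input_length)
    X <- .standardize_engine_raw(aperm(input, c(2L, 3L, 1L)))
    out <- .stack_forward(object$params, object$state, "s1", X, cfg, FALSE, "1d")
  } else {
    d <- dim(input)
    if (length(d) != 4L || d[2L] != cfg$input_channels ||
        d[3L] != cfg$spec_side || d[4L] != cfg$spec_side)
      stop("spectrogram input must be n x ", cfg$input_channels, " x ",
           cfg$spec_side, " x ", cfg$spec_side)
    X <- aperm(input, c(2L, 3L, 4L, 1L))
    dim(X) <- c(d[2L], d[3L] * d[4L], d[1L])
    out <- .stack_forward(object$params, object$state, "s2", X, cfg, FALSE, "2d")
  }
  t(out$E)
}
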