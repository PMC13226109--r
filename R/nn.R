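# Internal engine of the multi-stream staging network: parameter
# initialization, forward and backward passes, Adam. Convolutions and
# pooling run in compiled code (src/nn_ops.cpp); batch-norm, gating,
# dense layers and the optimizer are plain matrix algebra.
#
# Batch layout: raw (C, L, N) array; spectrogram (C2, side*side, N) with the
# H x W grid flattened column-major; handcrafted (D, N) matrix.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.he <- function(fan_in, dims) array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)

.nn_init <- function(cfg) {
  p <- list(); s <- list()
  add_conv_stack <- function(prefix, in_ch, channels, kernels) {
    for (i in seq_along(channels)) {
      cin <- if (i == 1) in_ch else channels[i - 1]
      k <- kernels[[i]]
      fan <- cin * prod(k)
      p[[paste0(prefix, ".conv", i, ".W")]] <<- matrix(.he(fan, c(channels[i] * fan)), channels[i], fan)
      p[[paste0(prefix, ".conv", i, ".b")]] <<- numeric(channels[i])
      p[[paste0(prefix, ".bn", i, ".gamma")]] <<- rep(1, channels[i])
      p[[paste0(prefix, ".bn", i, ".beta")]] <<- numeric(channels[i])
      s[[paste0(prefix, ".bn", i, ".mean")]] <<- numeric(channels[i])
      s[[paste0(prefix, ".bn", i, ".var")]] <<- rep(1, channels[i])
    }
  }
  add_conv_stack("s1", cfg$input_channels, cfg$conv1d$channels, as.list(cfg$conv1d$kernels))
  add_conv_stack("s2", cfg$input_channels, cfg$conv2d$channels,
                 lapply(cfg$conv2d$kernels, function(k) c(k, k)))
  fd <- cfg$fused_dim
  p$gate.W1 <- matrix(.he(fd, fd * cfg$gate_hidden), cfg$gate_hidden, fd)
  p$gate.b1 <- numeric(cfg$gate_hidden)
  p$gate.W2 <- matrix(.he(cfg$gate_hidden, cfg$gate_hidden * fd), fd, cfg$gate_hidden)
  p$gate.b2 <- numeric(fd)
  widths <- c(fd, cfg$classifier, cfg$n_classes)
  for (i in seq_len(length(widths) - 1L)) {
    p[[paste0("clf.W", i)]] <- matrix(.he(widths[i], widths[i] * widths[i + 1]),
                                      widths[i + 1], widths[i])
    p[[paste0("clf.b", i)]] <- numeric(widths[i + 1])
  }
  list(params = p, state = s)
}

.gap_forward <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1L], d[3L])
  for (n in seq_len(d[3L])) {
    sl <- x[, , n]
    if (is.null(dim(sl))) sl <- matrix(sl, d[1L], d[2L])
    out[, n] <- rowMeans(sl)
  }
  out
}

.gap_backward <- function(dE, L) {
  d <- dim(dE)
  aperm(array(dE / L, dim = c(d[1L], d[2L], L)), c(1L, 3L, 2L))
}

# forward through one conv stack; kind "1d" or "2d"
.stack_forward <- function(p, st, prefix, X, cfg, training, kind) {
  blocks <- if (kind == "1d") length(cfg$conv1d$channels) else length(cfg$conv2d$channels)
  cache <- list(X0 = X)
  if (kind == "2d") { H <- cfg$spec_side; W_ <- cfg$spec_side }
  for (i in seq_len(blocks)) {
    cW <- p[[paste0(prefix, ".conv", i, ".W")]]
    cb <- p[[paste0(prefix, ".conv", i, ".b")]]
    if (kind == "1d") {
      Z <- .cpp_conv1d_fwd(X, cW, cb, cfg$conv1d$strides[i])
    } else {
      k <- cfg$conv2d$kernels[i]
      Z <- .cpp_conv2d_fwd(X, cW, cb, H, W_, k, k)
    }
    bn <- .cpp_bn_fwd(Z, p[[paste0(prefix, ".bn", i, ".gamma")]],
                      p[[paste0(prefix, ".bn", i, ".beta")]],
                      st[[paste0(prefix, ".bn", i, ".mean")]],
                      st[[paste0(prefix, ".bn", i, ".var")]], training,
                      .BN_MOMENTUM, .BN_EPS)
    st[[paste0(prefix, ".bn", i, ".mean")]] <- as.numeric(bn$new_mean)
    st[[paste0(prefix, ".bn", i, ".var")]] <- as.numeric(bn$new_var)
    A <- .cpp_relu_fwd(bn$y)
    if (kind == "1d") {
      pl <- .cpp_maxpool1d_fwd(A, cfg$conv1d$pools[i])
    } else {
      pl <- .cpp_maxpool2d_fwd(A, H, W_, cfg$conv2d$pools[i])
      H <- H %/% cfg$conv2d$pools[i]; W_ <- W_ %/% cfg$conv2d$pools[i]
    }
    cache[[paste0("blk", i)]] <- list(Xin = X, bn_xhat = bn$xhat,
                                      bn_inv = as.numeric(bn$inv), A = A,
                                      idx = pl$idx, Lin = dim(A)[2L])
    X <- pl$Y
  }
  E <- .gap_forward(X)
  cache$pre_gap_len <- dim(X)[2L]
  list(E = E, cache = cache, state = st)
}

.stack_backward <- function(p, prefix, dE, cache, cfg, kind) {
  grads <- list()
  blocks <- if (kind == "1d") length(cfg$conv1d$channels) else length(cfg$conv2d$channels)
  dX <- .gap_backward(dE, cache$pre_gap_len)
  if (kind == "2d") {
    sides <- cfg$spec_side
    Hs <- integer(blocks)
    h <- cfg$spec_side
    for (i in seq_len(blocks)) { Hs[i] <- h; h <- h %/% cfg$conv2d$pools[i] }
  }
  for (i in rev(seq_len(blocks))) {
    ck <- cache[[paste0("blk", i)]]
    if (kind == "1d") {
      dA <- .cpp_maxpool1d_bwd(ck$idx, dX, ck$Lin)
    } else {
      dA <- .cpp_maxpool2d_bwd(ck$idx, dX, ck$Lin)
    }
    dBn <- .cpp_relu_bwd(dA, ck$A)
    bb <- .cpp_bn_bwd(dBn, ck$bn_xhat, ck$bn_inv,
                      p[[paste0(prefix, ".bn", i, ".gamma")]], TRUE)
    grads[[paste0(prefix, ".bn", i, ".gamma")]] <- as.numeric(bb$dgamma)
    grads[[paste0(prefix, ".bn", i, ".beta")]] <- as.numeric(bb$dbeta)
    cW <- p[[paste0(prefix, ".conv", i, ".W")]]
    if (kind == "1d") {
      cv <- .cpp_conv1d_bwd(ck$Xin, cW, bb$dx, cfg$conv1d$strides[i])
    } else {
      k <- cfg$conv2d$kernels[i]
      cv <- .cpp_conv2d_bwd(ck$Xin, cW, bb$dx, Hs[i], Hs[i], k, k)
    }
    grads[[paste0(prefix, ".conv", i, ".W")]] <- cv$dW
    grads[[paste0(prefix, ".conv", i, ".b")]] <- as.numeric(cv$db)
    dX <- cv$dX
  }
  grads
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.gate_forward <- function(p, z) {
  h_pre <- p$gate.W1 %*% z + p$gate.b1
  h <- pmax(h_pre, 0)
  s <- p$gate.W2 %*% h + p$gate.b2
  g <- .sigmoid(s)
  list(u = g * z, g = g, h = h, h_pre = h_pre, z = z)
}

.gate_backward <- function(p, du, cache) {
  dg <- du * cache$z
  dz <- du * cache$g
  ds <- dg * cache$g * (1 - cache$g)
  dW2 <- ds %*% t(cache$h)
  db2 <- rowSums(ds)
  dh <- t(p$gate.W2) %*% ds
  dh_pre <- dh * (cache$h_pre > 0)
  dW1 <- dh_pre %*% t(cache$z)
  db1 <- rowSums(dh_pre)
  dz <- dz + t(p$gate.W1) %*% dh_pre
  list(dz = dz, grads = list(gate.W1 = dW1, gate.b1 = db1,
                             gate.W2 = dW2, gate.b2 = db2))
}

.softmax <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

# full forward; batch = list(raw, spec, feat); returns probs + caches
.nn_forward <- function(p, st, batch, cfg, training = FALSE, dropout_masks = NULL) {
  s1 <- .stack_forward(p, st, "s1", batch$raw, cfg, training, "1d")
  st <- s1$state
  s2 <- .stack_forward(p, st, "s2", batch$spec, cfg, training, "2d")
  st <- s2$state
  z <- rbind(s1$E, s2$E, batch$feat)
  gt <- .gate_forward(p, z)
  n <- ncol(z)
  masks <- list()
  a <- gt$u
  dense_cache <- list()
  n_dense <- length(cfg$classifier)
  for (i in seq_len(n_dense)) {
    pre <- p[[paste0("clf.W", i)]] %*% a + p[[paste0("clf.b", i)]]
    act <- pmax(pre, 0)
    if (training && cfg$dropout[i] > 0) {
      mask <- if (is.null(dropout_masks)) {
        matrix(stats::rbinom(length(act), 1L, 1 - cfg$dropout[i]), nrow(act), n) /
          (1 - cfg$dropout[i])
      } else dropout_masks[[i]]
      out <- act * mask
    } else { mask <- NULL; out <- act }
    dense_cache[[i]] <- list(a_in = a, pre = pre, act = act, mask = mask)
    masks[[i]] <- mask
    a <- out
  }
  logits <- p[[paste0("clf.W", n_dense + 1L)]] %*% a + p[[paste0("clf.b", n_dense + 1L)]]
  probs <- .softmax(logits)
  list(probs = probs, logits = logits, state = st,
       cache = list(s1 = s1$cache, s2 = s2$cache, gate = gt,
                    dense = dense_cache, final_in = a, z = z),
       masks = masks)
}

# weighted cross-entropy; y in 0..2; w per-class weights
.nn_loss <- function(probs, y, w) {
  n <- ncol(probs)
  idx <- cbind(y + 1L, seq_len(n))
  py <- pmax(probs[idx], 1e-12)
  mean(w[y + 1L] * (-log(py)))
}

.nn_loss_grad <- function(probs, y, w) {
  n <- ncol(probs)
  onehot <- matrix(0, nrow(probs), n)
  onehot[cbind(y + 1L, seq_len(n))] <- 1
  sweep(probs - onehot, 2L, w[y + 1L], "*") / n
}

.nn_backward <- function(p, fwd, dlogits, cfg) {
  grads <- list()
  n_dense <- length(cfg$classifier)
  W_last <- paste0("clf.W", n_dense + 1L)
  grads[[W_last]] <- dlogits %*% t(fwd$cache$final_in)
  grads[[paste0("clf.b", n_dense + 1L)]] <- rowSums(dlogits)
  da <- t(p[[W_last]]) %*% dlogits
  for (i in rev(seq_len(n_dense))) {
    ck <- fwd$cache$dense[[i]]
    if (!is.null(ck$mask)) da <- da * ck$mask
    dpre <- da * (ck$pre > 0)
    grads[[paste0("clf.W", i)]] <- dpre %*% t(ck$a_in)
    grads[[paste0("clf.b", i)]] <- rowSums(dpre)
    da <- t(p[[paste0("clf.W", i)]]) %*% dpre
  }
  gb <- .gate_backward(p, da, fwd$cache$gate)
  grads <- c(grads, gb$grads)
  d1 <- cfg$embed_1d; d2 <- cfg$embed_2d
  dE1 <- gb$dz[seq_len(d1), , drop = FALSE]
  dE2 <- gb$dz[d1 + seq_len(d2), , drop = FALSE]
  grads <- c(grads, .stack_backward(p, "s1", dE1, fwd$cache$s1, cfg, "1d"))
  grads <- c(grads, .stack_backward(p, "s2", dE2, fwd$cache$s2, cfg, "2d"))
  grads
}

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
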