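test_that("analytic gradients match numerical gradients end to end", {
  set.seed(42)
  cfg <- tiny_net_config()
  ini <- somnifuse:::.nn_init(cfg)
  p <- ini$params; st <- ini$state
  n <- 5
  batch <- list(raw = array(rnorm(2 * 32 * n), c(2, 32, n)),
                spec = array(rnorm(2 * 64 * n), c(2, 64, n)),
                feat = matrix(rnorm(5 * n), 5, n))
  y <- c(0L, 1L, 2L, 1L, 0L)
  w <- c(1.2, 0.8, 1.5)
  lossfun <- function(pp)
    somnifuse:::.nn_loss(
      somnifuse:::.nn_forward(pp, st, batch, cfg, training = TRUE)$probs, y, w)
  fw <- somnifuse:::.nn_forward(p, st, batch, cfg, training = TRUE)
  gr <- somnifuse:::.nn_backward(
    p, fw, somnifuse:::.nn_loss_grad(fw$probs, y, w), cfg)
  eps <- 1e-5
  for (nm in names(p)) {
    expect_false(is.null(gr[[nm]]), info = nm)
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) / max(1e-6, abs(num), abs(gr[[nm]][i])),
                1e-3)
    }
  }
})

test_that("the dimension chain 64 + 64 + 65 = 193 is enforced and realized", {
  expect_error(msfnet_config(handcrafted_dim = 60), "dimension chain")
  m <- untrained_msfnet()
  s <- random_streams(3)
  e1 <- msfnet_embed(m, s$raw, "1d")
  e2 <- msfnet_embed(m, s$spec, "2d")
  expect_equal(dim(e1), c(3, 64))
  expect_equal(dim(e2), c(3, 64))
  gt <- somnifuse:::.gate_forward(m$params, rbind(t(e1), t(e2), t(s$feat)))
  expect_equal(nrow(gt$u), 193)
  expect_true(all(gt$g > 0 & gt$g < 1))
  expect_error(msfnet_embed(m, s$raw[, 1:5, , drop = FALSE], "1d"), "raw input")
})

test_that("forced gate weights give the identity and zero gates", {
  m <- untrained_msfnet()
  p <- m$params
  z <- matrix(rnorm(193 * 4), 193, 4)
  p$gate.W1[] <- 0; p$gate.b1[] <- 0; p$gate.W2[] <- 0
  p$gate.b2[] <- 30                      # sigmoid(30) ~ 1
  expect_equal(somnifuse:::.gate_forward(p, z)$u, z, tolerance = 1e-9)
  p$gate.b2[] <- -30                     # sigmoid(-30) ~ 0
  expect_equal(somnifuse:::.gate_forward(p, z)$u, 0 * z, tolerance = 1e-9)
})

test_that("classification is a softmax with lowest-index tie breaking", {
  probs <- somnifuse:::.softmax(matrix(c(0, 0, 0), 3, 1))
  expect_equal(as.numeric(probs), rep(1 / 3, 3))
  expect_equal(max.col(t(probs), ties.method = "first") - 1L, 0L)  # Wake
  p2 <- somnifuse:::.softmax(matrix(c(0, 10, 0), 3, 1))
  expect_gt(p2[2, 1], 0.99)
  set.seed(4)
  pr <- somnifuse:::.softmax(matrix(rnorm(3 * 50, sd = 4), 3))
  expect_equal(colSums(pr), rep(1, 50), tolerance = 1e-9)
  expect_true(all(pr >= 0))
})

test_that("class weights follow the inverse-frequency formula", {
  expect_equal(class_weights(c(600, 300, 100)),
               c(0.5556, 1.1111, 3.3333), tolerance = 1e-4)
  expect_equal(class_weights(c(100, 100, 100)), c(1, 1, 1))
  expect_error(class_weights(c(0, 1, 1)), "zero count")
})

test_that("weighted cross-entropy reduces to plain cross-entropy at unit weights", {
  set.seed(9)
  probs <- somnifuse:::.softmax(matrix(rnorm(3 * 40), 3))
  y <- sample(0:2, 40, replace = TRUE)
  plain <- mean(-log(probs[cbind(y + 1L, 1:40)]))
  expect_equal(somnifuse:::.nn_loss(probs, y, c(1, 1, 1)), plain, tolerance = 1e-12)
  # raising one class's weight strictly raises the loss when it is mispredicted
  w_hi <- c(1, 1, 3)
  expect_gt(somnifuse:::.nn_loss(probs, y, w_hi),
            somnifuse:::.nn_loss(probs, y, c(1, 1, 1)))
})

test_that("training is seeded-deterministic and can overfit separable data", {
  # separable toy streams: the handcrafted features carry the class signal
  n <- 180
  set.seed(77)
  y <- rep(0:2, length.out = n)
  s <- random_streams(n)
  for (i in seq_len(n)) s$feat[i, y[i] * 20 + 1:10] <- s$feat[i, y[i] * 20 + 1:10] + 4
  cfg <- msfnet_config(max_epochs = 8, patience = 8, batch_size = 32, seed = 13)
  fit1 <- msfnet(s, y, config = cfg)
  fit2 <- msfnet(s, y, config = cfg)
  expect_identical(fit1$history$val_macro_f1, fit2$history$val_macro_f1)
  pred <- predict(fit1, s)
  expect_identical(pred, predict(fit1, s))          # frozen-model determinism
  expect_gte(mean(pred == y), 0.99)                 # capacity / overfit check
  pr <- predict(fit1, s, type = "prob")
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-6)
  expect_error(msfnet(s, rep(5L, n), config = cfg), "labels")
})
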