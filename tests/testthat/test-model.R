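test_that("reference RNN matches a hand-unrolled recurrence", {
  d <- 3L; h <- 4L; Tt <- 5L; B <- 2L
  w <- random_rnn_weights(d, h, seed = 10)
  set.seed(11)
  x <- array(stats::rnorm(B * d * Tt), c(B, d, Tt))
  out <- rnn_forward_reference(x, w)
  # symbolic unroll, one instance and timestep at a time
  for (b in seq_len(B)) {
    hprev <- rep(0, h)
    for (t in seq_len(Tt)) {
      hprev <- tanh(as.numeric(x[b, , t] %*% w$Wx) +
                      as.numeric(hprev %*% w$Wh) + w$b)
      expect_equal(out[b, , t], hprev, tolerance = 1e-10)
    }
  }
  # single step closed form
  x1 <- array(stats::rnorm(B * d), c(B, d, 1))
  out1 <- rnn_forward_reference(x1, w)
  expect_equal(out1[, , 1],
               tanh(matrix(x1[, , 1], B, d) %*% w$Wx +
                      matrix(w$b, B, h, byrow = TRUE)),
               tolerance = 1e-12)
  # zero inputs, zero bias -> all-zero states
  w0 <- w; w0$b <- rep(0, h)
  expect_true(all(rnn_forward_reference(array(0, c(B, d, Tt)), w0) == 0))
})

test_that("fused RNN is equivalent to the reference across random shapes", {
  set.seed(20)
  worst <- 0
  for (rep in 1:100) {
    B <- sample(1:8, 1); d <- sample(1:12, 1); h <- sample(1:16, 1)
    Tt <- sample(c(1L, 2L, sample(3:40, 1), 64L), 1)
    w <- random_rnn_weights(d, h, seed = 1000 + rep, scale = 0.8)
    x <- array(stats::rnorm(B * d * Tt, sd = 2), c(B, d, Tt))
    diff <- max(abs(rnn_forward_reference(x, w) - rnn_forward_fused(x, w)))
    worst <- max(worst, diff)
  }
  expect_lte(worst, 1e-5)
  # zero weights match exactly
  wz <- list(Wx = matrix(0, 3, 4), Wh = matrix(0, 4, 4), b = rep(0, 4))
  xz <- array(stats::rnorm(2 * 3 * 5), c(2, 3, 5))
  expect_identical(rnn_forward_fused(xz, wz),
                   rnn_forward_reference(xz, wz))
})

test_that("RNN weight-shape mismatches are rejected", {
  w <- random_rnn_weights(3, 4)
  x <- array(0, c(2, 5, 3))
  expect_error(rnn_forward_reference(x, w), "inconsistent")
  expect_error(rnn_forward_fused(x, w), "inconsistent")
})

test_that("network gradients match numerical differentiation", {
  mc <- model_config("lightweight", rnn_hidden = 4)
  mc$conv_layers <- list(list(kf = 3L, kt = 3L, filters = 2L, stride = 1L))
  net <- ecgbeats:::build_beat_net(mc, n_bins = 6, seed = 2)
  set.seed(5)
  B <- 3L; Tt <- 5L
  batch <- array(stats::rnorm(6 * Tt * B), c(6, Tt, B))
  lengths <- c(5L, 3L, 4L)
  y <- c(1L, 3L, 5L)
  loss_fn <- function(n) {
    fwd <- ecgbeats:::beat_net_forward(n, mc, batch, lengths, TRUE)
    ecgbeats:::cross_entropy(fwd$probs, y)
  }
  fwd <- ecgbeats:::beat_net_forward(net, mc, batch, lengths, TRUE)
  grads <- ecgbeats:::beat_net_backward(fwd$net, mc, fwd$cache, fwd$probs, y)
  eps <- 1e-6
  for (k in names(net$params)) {
    p <- net$params[[k]]
    set.seed(100 + match(k, names(net$params)))
    for (i in sample(length(p), min(4, length(p)))) {
      np <- net; np$params[[k]][i] <- p[i] + eps
      nm <- net; nm$params[[k]][i] <- p[i] - eps
      num <- (loss_fn(np) - loss_fn(nm)) / (2 * eps)
      expect_equal(grads[[k]][i], num, tolerance = 1e-4,
                   label = sprintf("d/d%s[%d]", k, i))
    }
  }
})

test_that("softmax outputs are normalized probability rows", {
  mc <- model_config("lightweight", rnn_hidden = 8)
  net <- ecgbeats:::build_beat_net(mc, n_bins = 17, seed = 3)
  set.seed(6)
  batch <- array(stats::rnorm(17 * 12 * 4), c(17, 12, 4))
  fwd <- ecgbeats:::beat_net_forward(net, mc, batch, c(12L, 9L, 12L, 5L))
  expect_equal(rowSums(fwd$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fwd$probs >= 0))
})

test_that("outputs are invariant to extra zero padding", {
  mc <- model_config("lightweight", rnn_hidden = 8)
  net <- ecgbeats:::build_beat_net(mc, n_bins = 17, seed = 4)
  set.seed(7)
  lens <- c(9L, 6L, 11L)
  inst <- lapply(lens, function(l) matrix(stats::rnorm(17 * l), 17))
  p1 <- pad_batch(inst, 11L)
  p2 <- pad_batch(inst, 20L)
  f1 <- ecgbeats:::beat_net_forward(net, mc, p1$batch, p1$true_lengths)
  f2 <- ecgbeats:::beat_net_forward(net, mc, p2$batch, p2$true_lengths)
  expect_lt(max(abs(f1$probs - f2$probs)), 1e-6)
})

test_that("the lightweight network is smaller than the baseline", {
  lw <- model_config("lightweight", profile = "full")
  bl <- model_config("baseline", profile = "full")
  expect_lt(n_parameters(lw), n_parameters(bl))
  # also at matched desk widths
  expect_lt(n_parameters(model_config("lightweight")),
            n_parameters(model_config("baseline")))
})

test_that("full-scale training defaults follow the published recipe", {
  bl <- train_config("baseline", profile = "full")
  expect_equal(bl$learning_rate, 5e-6)
  expect_equal(bl$batch_size, 1000L)
  expect_equal(bl$epochs, 400L)
  lw <- train_config("lightweight", profile = "full")
  expect_equal(lw$learning_rate, 1e-5)
  expect_equal(lw$batch_size, 900L)
  expect_equal(lw$epochs, 300L)
  expect_equal(lw$selection_classes, c("N", "S", "V"))
  mc <- model_config("baseline", profile = "full")
  expect_equal(mc$rnn_hidden, 1760L)
  expect_equal(mc$rnn_layers, 2L)
  expect_equal(vapply(mc$conv_layers, function(l) c(l$kf, l$kt, l$filters),
                      integer(3)),
               matrix(c(3L, 11L, 11L, 3L, 3L, 11L), 3))
})

test_that("training reduces the loss and is seed-reproducible", {
  sg <- small_segments()
  keep <- seq_len(min(500, length(sg$x)))
  mc <- model_config("lightweight", rnn_hidden = 8)
  tc <- train_config("lightweight", epochs = 4, batch_size = 128, seed = 5,
                     rebalance = FALSE)  # mixture here is not N-majority
  fit1 <- train_beat_classifier(sg$x[keep], sg$labels[keep], mc, tc)
  expect_lt(fit1$history$loss[4], fit1$history$loss[1])
  fit2 <- train_beat_classifier(sg$x[keep], sg$labels[keep], mc, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  expect_error(train_beat_classifier(sg$x[1:5], rep("N", 5), mc, tc),
               "at least 2 classes")
})

test_that("prediction arg-max, tie-breaks and batch invariance behave", {
  sg <- small_segments()
  keep <- seq_len(min(400, length(sg$x)))
  fit <- train_beat_classifier(
    sg$x[keep], sg$labels[keep],
    model_config("lightweight", rnn_hidden = 8),
    train_config("lightweight", epochs = 2, batch_size = 128, seed = 6,
                 rebalance = FALSE))
  probs <- predict(fit, sg$x[keep[1:20]], type = "prob")
  cls <- predict(fit, sg$x[keep[1:20]])
  expect_equal(unname(cls[1:20]),
               AAMI_CLASSES[max.col(probs, ties.method = "first")])
  # batch predictions equal concatenated singleton predictions
  singles <- unlist(lapply(keep[1:10], function(i)
    predict(fit, sg$x[[i]])))
  expect_equal(unname(cls[1:10]), unname(singles))
  # raw (non-matrix) input is rejected
  expect_error(predict(fit, list(1:100)), "preprocess")
  # documented tie-break toward the earlier class
  expect_equal(AAMI_CLASSES[max.col(matrix(c(0.5, 0.5, 0, 0, 0), 1),
                                    ties.method = "first")], "N")
})
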