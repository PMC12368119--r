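test_that("forward pass honours the shape contracts", {
  w <- toy_windows(n = 8, n_time = 250)
  for (arch in c("CNN", "BiLSTM", "RNN", "MLP")) {
    cfg <- model_config(arch, window_length = 250, seed = 1)
    set.seed(1)
    p <- pupilevents:::init_params(cfg)
    f <- pupilevents:::model_forward(p, cfg, w$X)
    expect_length(f$logit, 8)
    expect_equal(dim(f$recon), c(8, 250))
  }

  # MLP merges temporal and feature dimensions: 250 * 3 = 750
  cfg <- model_config("MLP", window_length = 250, n_features = 3)
  expect_equal(pupilevents:::mlp_input_length(cfg), 750)
  # pupil-only ablation: 250
  cfg1 <- model_config("MLP", window_length = 250, n_features = 1)
  expect_equal(pupilevents:::mlp_input_length(cfg1), 250)

  # shape mismatch is rejected with a clear message
  cfg <- model_config("CNN", window_length = 250)
  set.seed(1)
  p <- pupilevents:::init_params(cfg)
  expect_error(pupilevents:::model_forward(p, cfg, toy_windows(4, 100)$X),
               "does not match")
})

test_that("CNN temporal sizes match the closed-form conv/pool arithmetic", {
  cfg <- model_config("CNN", window_length = 250)
  sizes <- pupilevents:::cnn_temporal_sizes(cfg)
  # independent oracle: valid conv (T - K + 1) then pool floor(T / 2)
  t <- 250; oracle <- integer(0)
  for (i in 1:4) { t <- (t - 5 + 1) %/% 2; oracle <- c(oracle, t) }
  expect_equal(sizes, oracle)
  expect_true(all(diff(sizes) < 0) && sizes[4] >= 1)
  # too-short windows are rejected at config time
  expect_error(model_config("CNN", window_length = 60), "too short")
})

test_that("cnn_layer matches a hand-computed kernel example", {
  # single channel, kernel (1,0,0,0,0): convolution is the identity shifted
  # to the window start, so the layer reduces to max pooling of pairs
  x <- array(c(5, 1, 4, 2, 8, 3, 9, 7, 2, 6), c(1, 10, 1))
  W <- matrix(c(1, 0, 0, 0, 0), 5, 1)
  y <- cnn_layer(x, W, b = 0)
  # conv output: x[1:6]; pooled pairs: max(5,1), max(4,2), max(8,3)
  expect_equal(as.numeric(y), c(5, 4, 8))

  # zero input, zero bias: ReLU(0) = 0
  y0 <- cnn_layer(array(0, c(2, 10, 1)), W, b = 0)
  expect_true(all(y0 == 0))

  # evaluation mode ignores the dropout rng
  set.seed(1); a <- cnn_layer(x, W, 0, dropout_rate = 0.5, training = FALSE)
  set.seed(2); b <- cnn_layer(x, W, 0, dropout_rate = 0.5, training = FALSE)
  expect_identical(a, b)

  expect_error(cnn_layer(array(0, c(1, 3, 1)), W, 0), "temporal length")
})

test_that("rnn_layer implements the linear recurrence exactly as specified", {
  # scalar toy: W_x = 1, W_h = 0.5, b = 0, x = 1,1,1 -> h3 = 1 + 0.5 + 0.25
  x <- array(1, c(1, 3, 1))
  y <- rnn_layer(x, Wx = matrix(1), Wh = matrix(0.5), b = 0)
  expect_equal(as.numeric(y[1, , 1]), c(1, 1.5, 1.75))

  # W_h = 0: the last output depends only on the last input
  x2 <- array(rnorm(6), c(1, 6, 1))
  y2 <- rnn_layer(x2, Wx = matrix(2), Wh = matrix(0), b = 1)
  expect_equal(y2[1, 6, 1], 2 * x2[1, 6, 1] + 1)

  # h_0 = 0: the first hidden state is just W_x x_1 + b
  expect_equal(y2[1, 1, 1], 2 * x2[1, 1, 1] + 1)
})

test_that("bilstm_layer concatenates directions and is time-reversal symmetric", {
  set.seed(3)
  H <- 4; Tn <- 5
  Wx <- matrix(runif(1 * 4 * H, -0.5, 0.5), 1, 4 * H)
  Wh <- matrix(runif(H * 4 * H, -0.5, 0.5), H, 4 * H)
  b <- numeric(4 * H)
  x <- array(rnorm(Tn), c(1, Tn, 1))

  y <- bilstm_layer(x, Wx, Wh, b, Wx, Wh, b)
  expect_equal(dim(y)[3], 2 * H)  # 64 + 64 in the full model

  # with identical weights in both directions, reversing time swaps the
  # roles of the two halves
  xr <- array(x[, Tn:1, , drop = FALSE], c(1, Tn, 1))
  yr <- bilstm_layer(xr, Wx, Wh, b, Wx, Wh, b)
  expect_equal(yr[, , 1:H], y[, Tn:1, H + 1:H], tolerance = 1e-12)
  expect_equal(yr[, , H + 1:H], y[, Tn:1, 1:H], tolerance = 1e-12)

  # zero weights give zero output
  z <- bilstm_layer(x, 0 * Wx, 0 * Wh, b, 0 * Wx, 0 * Wh, b)
  expect_true(all(z == 0))
})

test_that("mlp_layer is affine + ReLU with eval-mode determinism", {
  W <- matrix(c(1, -1), 1, 2); b <- c(0, 0.5)
  x <- matrix(c(2, -3), 2, 1)
  y <- mlp_layer(x, W, b)
  expect_equal(y, matrix(c(2, 0, 0, 3.5), 2, 2))
  expect_true(all(mlp_layer(matrix(0, 3, 1), W, c(0, 0)) == 0))
  set.seed(1); a <- mlp_layer(x, W, b, dropout_rate = 0.5, training = FALSE)
  expect_identical(a, y)
})

test_that("composite loss decomposes and matches an independent CE oracle", {
  set.seed(5)
  logit <- rnorm(4); recon <- matrix(rnorm(4 * 10), 4)
  labels <- c(0, 1, 1, 0); xpd <- matrix(rnorm(40), 4)

  l0 <- composite_loss(logit, recon, labels, xpd, alpha = 0)
  la <- composite_loss(logit, recon, labels, xpd, alpha = 0.004)
  mae <- mean(abs(pmax(recon, 0) - xpd))
  # exact decomposition: L(alpha) - L(0) = alpha * MAE
  expect_equal(as.numeric(la) - as.numeric(l0), 0.004 * mae, tolerance = 1e-12)

  # alpha = 0 equals a cross-entropy oracle via the Bernoulli density
  p <- stats::plogis(logit)
  ce_oracle <- -mean(stats::dbinom(labels, 1, p, log = TRUE))
  expect_equal(as.numeric(l0), ce_oracle, tolerance = 1e-9)

  # perfect prediction and reconstruction: loss vanishes (up to clamping)
  big <- c(-50, 50); lab <- c(0, 1); rc <- matrix(abs(rnorm(20)), 2)
  expect_lt(as.numeric(composite_loss(big, rc, lab, rc)), 1e-5)

  expect_error(composite_loss(logit, recon, c(0, 1, 2, 0), xpd), "0/1")
})

test_that("analytic gradients agree with finite differences", {
  for (arch in c("CNN", "MLP", "RNN", "BiLSTM")) {
    Tn <- if (arch == "BiLSTM") 20 else 100
    cfg <- model_config(arch, window_length = Tn, dropout_rate = 0, seed = 5)
    set.seed(2)
    p <- pupilevents:::init_params(cfg)
    X <- array(rnorm(2 * Tn * 3), c(2, Tn, 3))
    y <- c(0, 1); xpd <- matrix(X[, , 1], 2)
    lossf <- function(pp) {
      f <- pupilevents:::model_forward(pp, cfg, X)
      as.numeric(composite_loss(f$logit, f$recon, y, xpd, cfg$alpha))
    }
    f <- pupilevents:::model_forward(p, cfg, X, keep_cache = TRUE)
    g <- pupilevents:::composite_loss_grad(f$logit, f$recon, y, xpd, cfg$alpha)
    gr <- pupilevents:::model_backward(p, cfg, f, g$dlogit, g$drecon)
    for (nm in names(gr)) {
      i <- which.max(abs(gr[[nm]]))
      eps <- 1e-5
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- lossf(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- lossf(p2)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - gr[[nm]][i]) / max(abs(fd), abs(gr[[nm]][i]), 1e-8),
                1e-4)
    }
  }
})

test_that("evaluation mode is deterministic; training uses the seed", {
  w <- toy_windows(n = 8, n_time = 100)
  cfg <- model_config("CNN", window_length = 100, seed = 3)
  set.seed(1)
  p <- pupilevents:::init_params(cfg)
  set.seed(10); f1 <- pupilevents:::model_forward(p, cfg, w$X)
  set.seed(99); f2 <- pupilevents:::model_forward(p, cfg, w$X)
  expect_identical(f1$logit, f2$logit)
  expect_identical(f1$recon, f2$recon)
})

test_that("training reduces the loss and is reproducible; edge cases reject", {
  w <- toy_windows(n = 32, n_time = 100, offset = 0.8, seed = 9)
  cfg <- model_config("MLP", window_length = 100, max_epochs = 3,
                      patience = 10, batch_size = 16, seed = 7)
  m1 <- tepr_train(cfg, w, val = NULL)
  log1 <- tidy(m1)
  expect_true(all(diff(log1$train_loss[1:min(3, nrow(log1))]) < 0))

  m2 <- tepr_train(cfg, w, val = NULL)
  expect_identical(tidy(m2)$selection_mcc, log1$selection_mcc)
  expect_identical(m2$fingerprint, m1$fingerprint)

  expect_error(tepr_train(cfg, windows_subset(w, integer(0))), "empty")

  # glance returns the one-row summary
  gl <- glance(m1)
  expect_equal(gl$architecture, "MLP")
  expect_equal(gl$n_parameters, sum(vapply(m1$params, length, 1L)))
})

test_that("predictions are probabilities with a strict 0.5 threshold", {
  w <- toy_windows(n = 16, n_time = 100)
  cfg <- model_config("MLP", window_length = 100, max_epochs = 1, seed = 2)
  m <- tepr_train(cfg, w, val = NULL)
  pr <- predict(m, w)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_identical(pr$pred, as.integer(pr$prob > 0.5))

  # feature-count mismatch rejected
  w1 <- toy_windows(n = 4, n_time = 100, n_feat = 1)
  expect_error(predict(m, w1), "does not match")
})

test_that("untrained models hover around chance on balanced data", {
  w <- toy_windows(n = 200, n_time = 40, offset = 0, seed = 20)
  mccs <- vapply(1:5, function(s) {
    cfg <- model_config("MLP", window_length = 40, seed = s)
    set.seed(s)
    p <- pupilevents:::init_params(cfg)
    prob <- pupilevents:::predict_probs(p, cfg, w$X)
    mcc_value(confusion(w$meta$label, as.integer(prob > 0.5)))
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("pupil-only models run end-to-end", {
  w <- toy_windows(n = 24, n_time = 250, n_feat = 1, offset = 1)
  cfg <- model_config("CNN", n_features = 1, window_length = 250,
                      max_epochs = 3, patience = 5, batch_size = 24, seed = 1)
  m <- tepr_train(cfg, w, val = NULL)
  pr <- predict(m, w)
  expect_equal(nrow(pr), 24)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
})
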