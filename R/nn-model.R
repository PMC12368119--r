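#' Model configuration
#'
#' Hyperparameters of the shared two-headed architecture. Four stacked
#' architecture-specific layers feed a temporal average pooling (the last
#' hidden state for the RNN; skipped for the MLP, which sees the flattened
#' `window_length * n_features` input) and a single affine head emitting
#' `1 + window_length` values: one classification logit and a pupil-diameter
#' reconstruction used for error checking. Widths follow the reference
#' design: 64 convolution channels (kernel 5, stride 1, max pool 2), LSTM
#' hidden size 64 per direction, RNN hidden size 128, MLP hidden width 128,
#' dropout 0.3, reconstruction loss weight `alpha = 0.004`. Training defaults
#' (Adam, learning rate 1e-3, batch 64, early stopping on validation MCC)
#' are conventional desk-scale choices.
#'
#' @param architecture One of `"CNN"`, `"BiLSTM"`, `"RNN"`, `"MLP"`.
#' @param n_features Input channels: 3 (pupil + gaze) or 1 (pupil only).
#' @param window_length Samples per window (250 at 250 Hz and 1-s windows).
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param n_layers Number of stacked architecture-specific layers.
#' @param conv_filters,conv_kernel,pool_size CNN layer shape.
#' @param bilstm_hidden Hidden units per LSTM direction.
#' @param rnn_hidden,mlp_hidden Hidden widths of the RNN and MLP stacks.
#' @param rnn_nonlinearity `"identity"` runs the recurrence exactly as
#'   specified (no nonlinearity); `"tanh"` is offered as a variant.
#' @param alpha Weight of the reconstruction (mean absolute error) loss term.
#' @param learning_rate,batch_size,max_epochs,patience Training loop controls;
#'   `patience` is in epochs without validation-MCC improvement.
#' @param seed Seed for weight initialization, batch order and dropout.
#' @return A `tepr_model_config` list.
#' @export
model_config <- function(architecture = c("CNN", "BiLSTM", "RNN", "MLP"),
                         n_features = 3, window_length = 250,
                         dropout_rate = 0.3, n_layers = 4,
                         conv_filters = 64, conv_kernel = 5, pool_size = 2,
                         bilstm_hidden = 64, rnn_hidden = 128, mlp_hidden = 128,
                         rnn_nonlinearity = c("identity", "tanh"),
                         alpha = 0.004,
                         learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 100, patience = 10, seed = 0L) {
  architecture <- match.arg(architecture)
  rnn_nonlinearity <- match.arg(rnn_nonlinearity)
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must be in [0, 1)")
  if (alpha < 0) abort("`alpha` must be >= 0")
  if (!n_features %in% c(1, 3)) abort("`n_features` must be 1 or 3")
  out <- structure(list(
    architecture = architecture, n_features = n_features,
    window_length = as.integer(window_length),
    dropout_rate = dropout_rate, n_layers = as.integer(n_layers),
    conv_filters = conv_filters, conv_kernel = conv_kernel, pool_size = pool_size,
    bilstm_hidden = bilstm_hidden, rnn_hidden = rnn_hidden, mlp_hidden = mlp_hidden,
    rnn_nonlinearity = rnn_nonlinearity, alpha = alpha,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "tepr_model_config")
  if (architecture == "CNN") cnn_temporal_sizes(out)  # fail fast if too short
  out
}

# Flattened MLP input length: time and feature dimensions merged.
mlp_input_length <- function(cfg) cfg$window_length * cfg$n_features

# Temporal length after each CNN layer (valid conv then pool).
cnn_temporal_sizes <- function(cfg) {
  t <- cfg$window_length
  out <- integer(cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    t <- (t - cfg$conv_kernel + 1) %/% cfg$pool_size
    out[i] <- t
  }
  if (any(out < 1)) abort("window too short for the configured CNN stack")
  out
}

init_params <- function(cfg) {
  p <- list()
  gn <- function(nr, nc, sd) matrix(rnorm(nr * nc, 0, sd), nr, nc)
  if (cfg$architecture == "CNN") {
    cin <- cfg$n_features
    for (i in seq_len(cfg$n_layers)) {
      p[[paste0("l", i, ".W")]] <- gn(cfg$conv_kernel * cin, cfg$conv_filters,
                                      sqrt(2 / (cfg$conv_kernel * cin)))
      p[[paste0("l", i, ".b")]] <- numeric(cfg$conv_filters)
      cin <- cfg$conv_filters
    }
    head_in <- cfg$conv_filters
  } else if (cfg$architecture == "BiLSTM") {
    H <- cfg$bilstm_hidden
    k <- 1 / sqrt(H)
    cin <- cfg$n_features
    for (i in seq_len(cfg$n_layers)) {
      for (dir in c("fw", "bw")) {
        p[[paste0("l", i, ".", dir, ".Wx")]] <- matrix(runif(cin * 4 * H, -k, k), cin, 4 * H)
        p[[paste0("l", i, ".", dir, ".Wh")]] <- matrix(runif(H * 4 * H, -k, k), H, 4 * H)
        b <- numeric(4 * H); b[(H + 1):(2 * H)] <- 1  # forget-gate bias
        p[[paste0("l", i, ".", dir, ".b")]] <- b
      }
      cin <- 2 * H
    }
    head_in <- 2 * H
  } else if (cfg$architecture == "RNN") {
    H <- cfg$rnn_hidden
    cin <- cfg$n_features
    for (i in seq_len(cfg$n_layers)) {
      p[[paste0("l", i, ".Wx")]] <- gn(cin, H, sqrt(1 / cin))
      # small recurrent weights keep the as-printed linear recurrence stable
      p[[paste0("l", i, ".Wh")]] <- gn(H, H, 0.5 / sqrt(H))
      p[[paste0("l", i, ".b")]] <- numeric(H)
      cin <- H
    }
    head_in <- H
  } else {
    D <- mlp_input_length(cfg)
    for (i in seq_len(cfg$n_layers)) {
      p[[paste0("l", i, ".W")]] <- gn(D, cfg$mlp_hidden, sqrt(2 / D))
      p[[paste0("l", i, ".b")]] <- numeric(cfg$mlp_hidden)
      D <- cfg$mlp_hidden
    }
    head_in <- cfg$mlp_hidden
  }
  p[["head.W"]] <- gn(head_in, 1 + cfg$window_length, sqrt(1 / head_in))
  p[["head.b"]] <- numeric(1 + cfg$window_length)
  p
}

# ---- full forward pass ------------------------------------------------------
# Returns logits (B), reconstruction pre-activation (B x Tw) and, when
# `keep_cache`, everything the backward pass needs.

model_forward <- function(params, cfg, X, training = FALSE, keep_cache = FALSE) {
  if (length(dim(X)) != 3L) abort("X must be a (batch, time, feature) array")
  d <- dim(X)
  if (d[2] != cfg$window_length || d[3] != cfg$n_features) {
    abort(sprintf("input shape (%d, %d, %d) does not match config (*, %d, %d)",
                  d[1], d[2], d[3], cfg$window_length, cfg$n_features))
  }
  drop <- if (training) cfg$dropout_rate else 0
  caches <- vector("list", cfg$n_layers)
  A <- X

  if (cfg$architecture == "CNN") {
    for (i in seq_len(cfg$n_layers)) {
      cf <- conv1d_forward(A, params[[paste0("l", i, ".W")]], params[[paste0("l", i, ".b")]])
      pos <- cf$Y > 0
      pf <- maxpool_forward(cf$Y * pos)
      mask <- if (drop > 0) dropout_mask(dim(pf$Y), drop) else NULL
      A <- if (is.null(mask)) pf$Y else pf$Y * mask
      caches[[i]] <- list(conv = cf, pos = pos, pool = pf, mask = mask)
    }
    P <- temporal_mean(A)
  } else if (cfg$architecture == "BiLSTM") {
    for (i in seq_len(cfg$n_layers)) {
      fw <- lstm_forward(A, params[[paste0("l", i, ".fw.Wx")]],
                         params[[paste0("l", i, ".fw.Wh")]],
                         params[[paste0("l", i, ".fw.b")]], reverse = FALSE)
      bw <- lstm_forward(A, params[[paste0("l", i, ".bw.Wx")]],
                         params[[paste0("l", i, ".bw.Wh")]],
                         params[[paste0("l", i, ".bw.b")]], reverse = TRUE)
      H <- dim(fw$Y)[3]
      Y <- array(0, c(dim(A)[1], dim(A)[2], 2 * H))
      Y[, , seq_len(H)] <- fw$Y
      Y[, , H + seq_len(H)] <- bw$Y
      mask <- if (drop > 0) dropout_mask(dim(Y), drop) else NULL
      caches[[i]] <- list(fw = fw, bw = bw, A_in = A, mask = mask, H = H)
      A <- if (is.null(mask)) Y else Y * mask
    }
    P <- temporal_mean(A)
  } else if (cfg$architecture == "RNN") {
    for (i in seq_len(cfg$n_layers)) {
      mask <- if (drop > 0) {
        matrix(dropout_mask(c(d[1], cfg$rnn_hidden), drop), d[1], cfg$rnn_hidden)
      } else NULL
      rf <- rnn_forward(A, params[[paste0("l", i, ".Wx")]],
                        params[[paste0("l", i, ".Wh")]],
                        params[[paste0("l", i, ".b")]],
                        mask = mask, nonlinearity = cfg$rnn_nonlinearity)
      caches[[i]] <- list(rf = rf, A_in = A, mask = mask)
      A <- rf$Y
    }
    P <- A[, dim(A)[2], , drop = TRUE]  # y = last hidden state
    if (is.null(dim(P))) P <- matrix(P, nrow = d[1])
  } else {  # MLP: merge temporal and feature dimensions
    A <- matrix(X, nrow = d[1])
    for (i in seq_len(cfg$n_layers)) {
      Z <- sweep(A %*% params[[paste0("l", i, ".W")]], 2,
                 params[[paste0("l", i, ".b")]], "+")
      pos <- Z > 0
      mask <- if (drop > 0) matrix(dropout_mask(dim(Z), drop), nrow(Z), ncol(Z)) else NULL
      caches[[i]] <- list(A_in = A, pos = pos, mask = mask)
      A <- Z * pos
      if (!is.null(mask)) A <- A * mask
    }
    P <- A
  }

  out <- sweep(P %*% params[["head.W"]], 2, params[["head.b"]], "+")
  res <- list(logit = out[, 1], recon = out[, -1, drop = FALSE])
  if (keep_cache) res$cache <- list(layers = caches, P = P, X = X)
  res
}

temporal_mean <- function(A) {
  d <- dim(A)
  colSums(aperm(A, c(2, 1, 3))) / d[2]
}

model_backward <- function(params, cfg, fwd, dlogit, drecon) {
  cache <- fwd$cache
  B <- length(dlogit)
  dout <- cbind(dlogit, drecon)
  g <- list()
  g[["head.W"]] <- crossprod(cache$P, dout)
  g[["head.b"]] <- colSums(dout)
  dP <- tcrossprod(dout, params[["head.W"]])

  if (cfg$architecture == "CNN") {
    dA <- NULL
    for (i in rev(seq_len(cfg$n_layers))) {
      cc <- cache$layers[[i]]
      if (i == cfg$n_layers) {
        Tn <- dim(cc$pool$Y)[2]
        dA <- array(0, dim(cc$pool$Y))
        for (t in seq_len(Tn)) dA[, t, ] <- dP / Tn
      }
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      da <- maxpool_backward(dA, cc$pool)
      dz <- da * cc$pos
      cb <- conv1d_backward(dz, cc$conv, params[[paste0("l", i, ".W")]])
      g[[paste0("l", i, ".W")]] <- cb$dW
      g[[paste0("l", i, ".b")]] <- cb$db
      dA <- cb$dA
    }
  } else if (cfg$architecture == "BiLSTM") {
    dA <- NULL
    for (i in rev(seq_len(cfg$n_layers))) {
      cc <- cache$layers[[i]]
      if (i == cfg$n_layers) {
        d3 <- c(B, dim(cc$A_in)[2], 2 * cc$H)
        dA <- array(0, d3)
        for (t in seq_len(d3[2])) dA[, t, ] <- dP / d3[2]
      }
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      H <- cc$H
      bf <- lstm_backward(dA[, , seq_len(H), drop = FALSE], cc$fw,
                          params[[paste0("l", i, ".fw.Wx")]],
                          params[[paste0("l", i, ".fw.Wh")]])
      bb <- lstm_backward(dA[, , H + seq_len(H), drop = FALSE], cc$bw,
                          params[[paste0("l", i, ".bw.Wx")]],
                          params[[paste0("l", i, ".bw.Wh")]])
      g[[paste0("l", i, ".fw.Wx")]] <- bf$dWx
      g[[paste0("l", i, ".fw.Wh")]] <- bf$dWh
      g[[paste0("l", i, ".fw.b")]] <- bf$db
      g[[paste0("l", i, ".bw.Wx")]] <- bb$dWx
      g[[paste0("l", i, ".bw.Wh")]] <- bb$dWh
      g[[paste0("l", i, ".bw.b")]] <- bb$db
      dA <- bf$dA + bb$dA
    }
  } else if (cfg$architecture == "RNN") {
    dA <- NULL
    for (i in rev(seq_len(cfg$n_layers))) {
      cc <- cache$layers[[i]]
      if (i == cfg$n_layers) {
        dA <- array(0, dim(cc$rf$Y))
        dA[, dim(dA)[2], ] <- dP
      }
      rb <- rnn_backward(dA, cc$rf, cc$A_in,
                         params[[paste0("l", i, ".Wx")]],
                         params[[paste0("l", i, ".Wh")]],
                         mask = cc$mask, nonlinearity = cfg$rnn_nonlinearity)
      g[[paste0("l", i, ".Wx")]] <- rb$dWx
      g[[paste0("l", i, ".Wh")]] <- rb$dWh
      g[[paste0("l", i, ".b")]] <- rb$db
      dA <- rb$dA
    }
  } else {
    dA <- dP
    for (i in rev(seq_len(cfg$n_layers))) {
      cc <- cache$layers[[i]]
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      dz <- dA * cc$pos
      g[[paste0("l", i, ".W")]] <- crossprod(cc$A_in, dz)
      g[[paste0("l", i, ".b")]] <- colSums(dz)
      dA <- tcrossprod(dz, params[[paste0("l", i, ".W")]])
    }
  }
  g
}

#' Composite classification + reconstruction loss
#'
#' Binary cross-entropy between the sigmoid of the classification logit and
#' the label, plus `alpha` times the mean absolute error between the
#' rectified (ReLU) reconstruction and the window's pupil-diameter channel.
#' Probabilities are clamped to `[eps, 1 - eps]` before the log for numerical
#' safety.
#'
#' @param logit Numeric vector of classification logits.
#' @param recon Matrix `(batch, window_length)` of reconstruction
#'   pre-activations.
#' @param labels 0/1 vector.
#' @param x_pd Matrix `(batch, window_length)`: the true (standardized) pupil
#'   channel.
#' @param alpha Reconstruction weight (default 0.004).
#' @param eps Clamping constant.
#' @return Scalar loss with attributes `"ce"` and `"mae"` (its two parts).
#' @export
composite_loss <- function(logit, recon, labels, x_pd, alpha = 0.004, eps = 1e-7) {
  if (any(!labels %in% c(0, 1))) abort("labels must be 0/1")
  p <- pmin(pmax(stats::plogis(logit), eps), 1 - eps)
  ce <- mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
  mae <- mean(abs(pmax(recon, 0) - x_pd))
  structure(ce + alpha * mae, ce = ce, mae = mae)
}

# Loss gradients wrt logit and recon (mean-reduced over the batch).
composite_loss_grad <- function(logit, recon, labels, x_pd, alpha = 0.004) {
  B <- length(logit)
  dlogit <- (stats::plogis(logit) - labels) / B
  pos <- recon > 0
  drecon <- alpha * sign(pmax(recon, 0) - x_pd) * pos / (B * ncol(recon))
  list(dlogit = dlogit, drecon = drecon)
}
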