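# Layer primitives for the four architectures. Each primitive has a forward
# pass that returns its output plus a cache, and a matching backward pass
# returning input and parameter gradients. Inputs are batch-first arrays
# (batch x time x channel) except the dense layer (batch x feature).
# Dropout uses the inverted convention (scaling by 1/keep at train time) so
# evaluation is exactly the identity.

dropout_mask <- function(dm, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  array((runif(prod(dm)) < keep) / keep, dm)
}

# ---- 1-D convolution (valid padding, stride 1) via im2col ------------------

im2col <- function(A, K) {
  d <- dim(A)  # B, T, C
  To <- d[2] - K + 1
  M <- matrix(0, d[1] * To, K * d[3])
  for (k in seq_len(K)) {
    blk <- A[, k:(k + To - 1), , drop = FALSE]
    dim(blk) <- c(d[1] * To, d[3])
    M[, ((k - 1) * d[3] + 1):(k * d[3])] <- blk
  }
  M
}

conv1d_forward <- function(A, W, b) {
  d <- dim(A)
  K <- nrow(W) / d[3]
  if (d[2] < K) abort(sprintf("temporal length %d < kernel size %d", d[2], K))
  M <- im2col(A, K)
  Y <- sweep(M %*% W, 2, b, "+")
  To <- d[2] - K + 1
  dim(Y) <- c(d[1], To, ncol(W))
  list(Y = Y, M = M, in_dim = d, K = K)
}

conv1d_backward <- function(dY, cache, W) {
  d <- cache$in_dim
  To <- d[2] - cache$K + 1
  dYm <- matrix(dY, d[1] * To, dim(dY)[3])
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  dA <- array(0, d)
  for (k in seq_len(cache$K)) {
    blk <- dM[, ((k - 1) * d[3] + 1):(k * d[3]), drop = FALSE]
    dim(blk) <- c(d[1], To, d[3])
    dA[, k:(k + To - 1), ] <- dA[, k:(k + To - 1), , drop = FALSE] + blk
  }
  list(dA = dA, dW = dW, db = db)
}

# ---- max pooling over time, size 2, stride 2 -------------------------------

maxpool_forward <- function(A) {
  d <- dim(A)
  Tp <- d[2] %/% 2
  A1 <- A[, seq(1, 2 * Tp, by = 2), , drop = FALSE]
  A2 <- A[, seq(2, 2 * Tp, by = 2), , drop = FALSE]
  first <- A1 >= A2  # ties go to the earlier sample
  list(Y = ifelse(first, A1, A2), first = first, in_dim = d)
}

maxpool_backward <- function(dY, cache) {
  d <- cache$in_dim
  Tp <- d[2] %/% 2
  dA <- array(0, d)
  dA[, seq(1, 2 * Tp, by = 2), ] <- dY * cache$first
  dA[, seq(2, 2 * Tp, by = 2), ] <- dY * !cache$first
  dA
}

# ---- LSTM (single direction) -----------------------------------------------
# Gate layout in the weight columns: [input, forget, cell, output].

lstm_forward <- function(A, Wx, Wh, b, reverse = FALSE) {
  d <- dim(A)  # B, T, C
  H <- ncol(Wh) / 4
  ts <- if (reverse) rev(seq_len(d[2])) else seq_len(d[2])
  h <- matrix(0, d[1], H); cc <- matrix(0, d[1], H)
  Hseq <- array(0, c(d[1], d[2], H))
  cache <- vector("list", d[2])
  sig <- stats::plogis
  for (step in seq_along(ts)) {
    t <- ts[step]
    xt <- A[, t, , drop = FALSE]; dim(xt) <- c(d[1], d[3])
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, "+")
    i <- sig(z[, 1:H, drop = FALSE])
    f <- sig(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sig(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    Hseq[, t, ] <- h
    cache[[step]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                          i = i, f = f, g = g, o = o, tc = tc)
  }
  list(Y = Hseq, cache = cache, ts = ts, in_dim = d)
}

lstm_backward <- function(dY, fwd, Wx, Wh) {
  d <- fwd$in_dim
  H <- dim(dY)[3]
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * H)
  dA <- array(0, d)
  dh <- matrix(0, d[1], H); dc <- matrix(0, d[1], H)
  for (step in rev(seq_along(fwd$ts))) {
    t <- fwd$ts[step]
    cc <- fwd$cache[[step]]
    dht <- dY[, t, , drop = FALSE]; dim(dht) <- c(d[1], H)
    dh <- dh + dht
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dA[, t, ] <- dA[, t, ] + tcrossprod(dz, Wx)
    dh <- tcrossprod(dz, Wh)
    dc <- dc * cc$f
  }
  list(dA = dA, dWx = dWx, dWh = dWh, db = db)
}

# ---- simple recurrence (linear as printed; optional tanh) ------------------

rnn_forward <- function(A, Wx, Wh, b, mask = NULL, nonlinearity = "identity") {
  d <- dim(A)
  H <- ncol(Wh)
  h <- matrix(0, d[1], H)  # h_0 = 0
  Hseq <- array(0, c(d[1], d[2], H))
  Zs <- if (nonlinearity == "tanh") array(0, c(d[1], d[2], H)) else NULL
  for (t in seq_len(d[2])) {
    xt <- A[, t, , drop = FALSE]; dim(xt) <- c(d[1], d[3])
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, "+")
    a <- if (nonlinearity == "tanh") tanh(z) else z
    if (!is.null(Zs)) Zs[, t, ] <- z
    h <- if (is.null(mask)) a else a * mask
    Hseq[, t, ] <- h
  }
  list(Y = Hseq, Zs = Zs, in_dim = d)
}

rnn_backward <- function(dY, fwd, A, Wx, Wh, mask = NULL, nonlinearity = "identity") {
  d <- fwd$in_dim
  H <- ncol(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, H, H)
  db <- numeric(H)
  dA <- array(0, d)
  dh_rec <- matrix(0, d[1], H)
  for (t in rev(seq_len(d[2]))) {
    dht <- dY[, t, , drop = FALSE]; dim(dht) <- c(d[1], H)
    dh <- dht + dh_rec
    da <- if (is.null(mask)) dh else dh * mask
    dz <- if (nonlinearity == "tanh") da * (1 - tanh(fwd$Zs[, t, ])^2) else da
    xt <- A[, t, , drop = FALSE]; dim(xt) <- c(d[1], d[3])
    h_prev <- if (t > 1) {
      hp <- fwd$Y[, t - 1, , drop = FALSE]; dim(hp) <- c(d[1], H); hp
    } else matrix(0, d[1], H)
    dWx <- dWx + crossprod(xt, dz)
    dWh <- dWh + crossprod(h_prev, dz)
    db <- db + colSums(dz)
    dA[, t, ] <- dA[, t, ] + tcrossprod(dz, Wx)
    dh_rec <- tcrossprod(dz, Wh)
  }
  list(dA = dA, dWx = dWx, dWh = dWh, db = db)
}

# ---- user-facing single-layer wrappers -------------------------------------

#' Single layers of the four architectures
#'
#' Standalone forward passes of the building-block layers:
#' `cnn_layer()` applies a valid 1-D convolution (stride 1), ReLU, max pooling
#' of size 2 and dropout; `bilstm_layer()` concatenates a forward and a
#' backward LSTM pass; `rnn_layer()` runs the simple recurrence
#' `h_t = M (W_x x_t + W_h h_{t-1} + b)` from `h_0 = 0` — linear as specified,
#' with an optional `tanh` — and returns the full hidden sequence;
#' `mlp_layer()` is affine + ReLU + dropout. Dropout is inactive unless
#' `training = TRUE`, so evaluation is deterministic.
#'
#' @param x Input array `(batch, time, channels)`; for `mlp_layer()` a matrix
#'   `(batch, features)`.
#' @param W,b Convolution/affine weights. For `cnn_layer()` `W` is
#'   `(kernel * in_channels) x out_channels`, rows ordered kernel-position
#'   major.
#' @param Wx,Wh Input and recurrent weight matrices.
#' @param Wx_f,Wh_f,b_f,Wx_b,Wh_b,b_b Forward/backward LSTM weights; columns
#'   are the stacked input/forget/cell/output gates.
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param training Draw a dropout mask? (`FALSE` = identity.)
#' @param nonlinearity `"identity"` (as specified) or `"tanh"`.
#' @return The layer output (array or matrix).
#' @export
cnn_layer <- function(x, W, b, dropout_rate = 0, training = FALSE) {
  cf <- conv1d_forward(x, W, b)
  a <- pmax(cf$Y, 0)
  pf <- maxpool_forward(a)
  y <- pf$Y
  if (training && dropout_rate > 0) y <- y * dropout_mask(dim(y), dropout_rate)
  y
}

#' @rdname cnn_layer
#' @export
bilstm_layer <- function(x, Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b,
                         dropout_rate = 0, training = FALSE) {
  f <- lstm_forward(x, Wx_f, Wh_f, b_f, reverse = FALSE)
  b <- lstm_forward(x, Wx_b, Wh_b, b_b, reverse = TRUE)
  d <- dim(f$Y)
  y <- array(0, c(d[1], d[2], 2 * d[3]))
  y[, , seq_len(d[3])] <- f$Y
  y[, , d[3] + seq_len(d[3])] <- b$Y
  if (training && dropout_rate > 0) y <- y * dropout_mask(dim(y), dropout_rate)
  y
}

#' @rdname cnn_layer
#' @export
rnn_layer <- function(x, Wx, Wh, b, dropout_rate = 0, training = FALSE,
                      nonlinearity = "identity") {
  mask <- if (training && dropout_rate > 0) {
    matrix(dropout_mask(c(dim(x)[1], ncol(Wh)), dropout_rate),
           dim(x)[1], ncol(Wh))
  } else NULL
  rnn_forward(x, Wx, Wh, b, mask = mask, nonlinearity = nonlinearity)$Y
}

#' @rdname cnn_layer
#' @export
mlp_layer <- function(x, W, b, dropout_rate = 0, training = FALSE) {
  y <- pmax(sweep(x %*% W, 2, b, "+"), 0)
  if (training && dropout_rate > 0) y <- y * dropout_mask(dim(y), dropout_rate)
  y
}
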