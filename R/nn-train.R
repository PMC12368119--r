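# Training loop: Adam on the composite loss, early stopping on validation
# MCC, best-epoch weight selection. All randomness (init, batch order,
# dropout) flows from the config seed, so repeat runs are identical.

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

windows_to_xy <- function(w, cfg) {
  if (dim(w$X)[2] != cfg$window_length || dim(w$X)[3] != cfg$n_features) {
    abort(sprintf("window geometry (%d x %d) does not match config (%d x %d)",
                  dim(w$X)[2], dim(w$X)[3], cfg$window_length, cfg$n_features))
  }
  list(X = w$X, y = w$meta$label, x_pd = matrix(w$X[, , 1], dim(w$X)[1]))
}

weights_fingerprint <- function(params) {
  v <- unlist(params, use.names = FALSE)
  sprintf("%.10e", sum(v * sin(seq_along(v))))
}

#' Train a cognitive-event detection model
#'
#' Minimizes the composite loss ([composite_loss()]) by mini-batch Adam.
#' After each epoch the model is evaluated on the validation windows (MCC of
#' thresholded probabilities); the weights of the best validation epoch are
#' kept, and training stops early after `patience` epochs without
#' improvement. With `val = NULL` (e.g. toy capacity runs) training MCC
#' drives selection instead. The training set is expected SMOTE-balanced; the
#' validation set must be untouched by SMOTE.
#'
#' @param config A [model_config()].
#' @param train,val `tepr_windows` sets (`val` may be `NULL`).
#' @param quiet Suppress the per-epoch progress messages?
#' @return A `tepr_model`: list with the config, fitted weights, a per-epoch
#'   `training_log` tibble, the selected epoch and a weights fingerprint.
#' @export
tepr_train <- function(config, train, val = NULL, quiet = TRUE) {
  if (n_windows(train) == 0L) abort("empty training set")
  tr <- windows_to_xy(train, config)
  va <- if (!is.null(val) && n_windows(val) > 0) windows_to_xy(val, config) else NULL

  with_seed(config$seed, {
    params <- init_params(config)
    state <- adam_init(params)
    n <- dim(tr$X)[1]
    best <- list(mcc = -Inf, params = params, epoch = 0L)
    log <- vector("list", config$max_epochs)
    stale <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        Xb <- tr$X[b, , , drop = FALSE]
        fwd <- model_forward(params, config, Xb, training = TRUE, keep_cache = TRUE)
        loss <- composite_loss(fwd$logit, fwd$recon, tr$y[b],
                               tr$x_pd[b, , drop = FALSE], config$alpha)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d; last finite batch losses: %s",
                        epoch, paste(utils::tail(round(losses, 4), 3), collapse = ", ")))
        }
        gr <- composite_loss_grad(fwd$logit, fwd$recon, tr$y[b],
                                  tr$x_pd[b, , drop = FALSE], config$alpha)
        grads <- model_backward(params, config, fwd, gr$dlogit, gr$drecon)
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, as.numeric(loss))
      }
      sel <- if (!is.null(va)) {
        p <- predict_probs(params, config, va$X)
        mcc_value(confusion(va$y, as.integer(p > 0.5)))
      } else {
        p <- predict_probs(params, config, tr$X)
        mcc_value(confusion(tr$y, as.integer(p > 0.5)))
      }
      log[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                             selection_mcc = sel,
                             selection_on = if (is.null(va)) "train" else "val")
      if (!quiet) inform(sprintf("epoch %3d  loss %.4f  %s MCC %.3f",
                                 epoch, mean(losses),
                                 if (is.null(va)) "train" else "val", sel))
      if (sel > best$mcc + 1e-12) {
        best <- list(mcc = sel, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
      if (is.null(va) && sel >= 1) break  # toy runs: nothing left to learn
    }

    structure(list(
      config = config, params = best$params,
      training_log = purrr::list_rbind(log[!purrr::map_lgl(log, is.null)]),
      best_epoch = best$epoch, best_selection_mcc = best$mcc,
      fingerprint = weights_fingerprint(best$params)
    ), class = "tepr_model")
  })
}

predict_probs <- function(params, cfg, X, chunk = 512L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (i in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fwd <- model_forward(params, cfg, X[i, , , drop = FALSE], training = FALSE)
    out[i] <- stats::plogis(fwd$logit)
  }
  out
}

#' Predict event probabilities for windows
#'
#' Runs the fitted model in evaluation mode (dropout off, fully
#' deterministic) and thresholds the sigmoid probability at 0.5; a
#' probability of exactly 0.5 maps to class 0.
#'
#' @param object A `tepr_model`.
#' @param windows A `tepr_windows` set with matching geometry.
#' @param ... Unused.
#' @return A tibble with columns `window_id`, `participant_id`, `task`,
#'   `label`, `prob`, `pred`.
#' @export
predict.tepr_model <- function(object, windows, ...) {
  xy <- windows_to_xy(windows, object$config)
  prob <- predict_probs(object$params, object$config, xy$X)
  tibble(
    window_id = windows$meta$window_id,
    participant_id = windows$meta$participant_id,
    task = windows$meta$task,
    label = windows$meta$label,
    prob = prob,
    pred = as.integer(prob > 0.5)
  )
}

#' @export
print.tepr_model <- function(x, ...) {
  cat(sprintf("<tepr_model> %s, %d params, best epoch %d (selection MCC %.3f)\n",
              x$config$architecture,
              sum(purrr::map_int(x$params, length)),
              x$best_epoch, x$best_selection_mcc))
  invisible(x)
}

#' Tidy / glance methods for fitted models
#'
#' `tidy()` returns the per-epoch training log; `glance()` a one-row model
#' summary.
#'
#' @param x A `tepr_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tepr_model
#' @export
tidy.tepr_model <- function(x, ...) x$training_log

#' @rdname tidy.tepr_model
#' @method glance tepr_model
#' @export
glance.tepr_model <- function(x, ...) {
  tibble(
    architecture = x$config$architecture,
    n_parameters = sum(purrr::map_int(x$params, length)),
    n_features = x$config$n_features,
    window_length = x$config$window_length,
    epochs_run = nrow(x$training_log),
    best_epoch = x$best_epoch,
    best_selection_mcc = x$best_selection_mcc,
    fingerprint = x$fingerprint
  )
}
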