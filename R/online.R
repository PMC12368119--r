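# Online streaming simulation: causal replay of a recording with an
# incrementally updated normalization baseline and fixed-stride
# sliding-window prediction.

#' Streaming normalization state
#'
#' Per-feature running mean and standard deviation maintained with Welford's
#' numerically stable single-pass update. Missing samples are skipped without
#' corrupting the moments.
#'
#' @param features Feature names tracked by the state.
#' @return A `tepr_stream_state`.
#' @export
stream_state_new <- function(features = c("pupil", "gaze_x", "gaze_y")) {
  structure(list(
    features = features,
    n = setNames(numeric(length(features)), features),
    mean = setNames(numeric(length(features)), features),
    m2 = setNames(numeric(length(features)), features)
  ), class = "tepr_stream_state")
}

#' @rdname stream_state_new
#' @param state A `tepr_stream_state`.
#' @param sample Named numeric vector (one value per feature; `NA` skipped).
#' @export
update_baseline <- function(state, sample) {
  for (f in state$features) {
    x <- sample[[f]]
    if (is.na(x)) next
    state$n[[f]] <- state$n[[f]] + 1
    delta <- x - state$mean[[f]]
    state$mean[[f]] <- state$mean[[f]] + delta / state$n[[f]]
    state$m2[[f]] <- state$m2[[f]] + delta * (x - state$mean[[f]])
  }
  state
}

#' @rdname stream_state_new
#' @export
stream_moments <- function(state) {
  tibble(
    feature = state$features,
    n = as.numeric(state$n),
    mean = ifelse(state$n > 0, state$mean, NA_real_),
    sd = ifelse(state$n > 1, sqrt(state$m2 / pmax(state$n - 1, 1)), NA_real_)
  )
}

#' Sliding-window streaming prediction
#'
#' Replays one recording as a causal stream: the first `warmup` seconds feed
#' the normalization baseline only; from `warmup + window_duration` on, a
#' prediction is emitted every `stride` seconds from the trailing window,
#' normalized with the running baseline available at that moment (the
#' baseline keeps updating for the whole stream). A prediction at time t uses
#' only samples with timestamps <= t. Windows containing missing samples
#' yield `NA` probabilities flagged in the trace.
#'
#' @param model A `tepr_model`.
#' @param rec A `tepr_recording` or a samples tibble of one recording.
#' @param stride Prediction period in seconds (default 0.1).
#' @param warmup Baseline warm-up in seconds (default 60).
#' @return A `tepr_online_trace` tibble: `time_s`, `prob`, `missing`;
#'   attributes `stride`, `events` (onset times, if known), `threshold`.
#' @export
stream_predict <- function(model, rec, stride = 0.1, warmup = 60) {
  samples <- if (inherits(rec, "tepr_recording")) rec$samples else rec
  events <- if (inherits(rec, "tepr_recording")) rec$events$stimulus_time_s else numeric(0)
  feats <- c("pupil", "gaze_x", "gaze_y")[seq_len(model$config$n_features)]
  cols <- c("pupil_mm", "gaze_x", "gaze_y")[seq_len(model$config$n_features)]

  fs <- round(1 / median(diff(samples$time_s)))
  n_win <- model$config$window_length
  duration <- n_win / fs
  t_end <- nrow(samples) / fs
  if (t_end < warmup + duration) {
    abort(sprintf("recording too short for streaming: %.1f s < warmup %.1f s + window %.1f s",
                  t_end, warmup, duration))
  }
  vals <- as.matrix(samples[, cols])
  pred_times <- seq(warmup + duration, t_end, by = stride)
  step <- stride * fs

  state <- stream_state_new(feats)
  cursor <- 0L
  wins <- array(NA_real_, c(length(pred_times), n_win, length(feats)))
  missing <- logical(length(pred_times))
  sd_warned <- FALSE

  for (k in seq_along(pred_times)) {
    upto <- round(pred_times[k] * fs)
    if (upto > cursor) {
      for (i in (cursor + 1L):min(upto, nrow(vals))) {
        state <- update_baseline(state, setNames(vals[i, ], feats))
      }
      cursor <- min(upto, nrow(vals))
    }
    idx <- (upto - n_win + 1L):upto
    win <- vals[idx, , drop = FALSE]
    if (anyNA(win)) {
      missing[k] <- TRUE
      next
    }
    mom <- stream_moments(state)
    s <- mom$sd
    if (any(!is.finite(s) | s == 0)) {
      if (!sd_warned) {
        inform("stream_predict: degenerate running sd; falling back to sd = 1 for affected features")
        sd_warned <- TRUE
      }
      s[!is.finite(s) | s == 0] <- 1
    }
    wins[k, , ] <- sweep(sweep(win, 2, mom$mean, "-"), 2, s, "/")
  }

  prob <- rep(NA_real_, length(pred_times))
  live <- which(!missing)
  if (length(live) > 0) {
    prob[live] <- predict_probs(model$params, model$config,
                                wins[live, , , drop = FALSE])
  }
  structure(
    tibble(time_s = pred_times, prob = prob, missing = missing),
    stride = stride, events = events, threshold = 0.5,
    class = c("tepr_online_trace", class(tibble()))
  )
}

# Upward 0.5-crossings, debounced two ways: a crossing only counts when the
# probability holds above threshold for at least `min_hold` seconds
# (transient single-stride blips are not events), and crossings closer than
# `debounce` seconds to the previous kept one collapse into a single
# detection. Crossings are computed on the live (non-missing) subsequence,
# so a stream that resumes above threshold after a dropout gap does not
# count as a new crossing unless the last live prediction before the gap
# was below it.
trace_detections <- function(trace, threshold = 0.5, debounce = 0.5,
                             min_hold = 0.2) {
  live <- !is.na(trace$prob)
  p <- trace$prob[live]
  tl <- trace$time_s[live]
  stride <- attr(trace, "stride") %||% 0.1
  runs <- rle(p > threshold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= max(1, ceiling(min_hold / stride))
  cross <- tl[starts[keep]]
  if (length(cross) == 0) return(numeric(0))
  kept <- cross[1]
  for (t in cross[-1]) if (t - kept[length(kept)] >= debounce) kept <- c(kept, t)
  kept
}

#' Score an online trace against the true onsets
#'
#' Mirrors the offline labeling geometry: an onset counts as a true positive
#' when at least one upward 0.5-crossing of the probability falls inside
#' `[onset + 0.5, onset + 0.5 + duration + latency]` — the `latency`
#' allowance reflects that a causal detector can only cross once its
#' trailing window has seen enough of the response; the pre-onset interval
#' `[onset - duration, onset)` is a negative trial (false positive if it
#' contains a crossing, true negative otherwise); crossings outside every
#' scored interval are additional false positives. Only onsets whose scoring
#' intervals lie inside the prediction range are scored, and — mirroring the
#' offline rule that windows containing missing samples are removed rather
#' than classified — intervals overlapping missing predictions are excluded
#' from scoring.
#'
#' @param trace A `tepr_online_trace`.
#' @param stimulus_times Onset times in seconds; defaults to the events
#'   stored in the trace.
#' @param duration Window duration in seconds.
#' @param latency Detection-latency allowance in seconds.
#' @return A [metric_report()] row, with detections in attribute
#'   `"detections"`.
#' @export
score_online <- function(trace, stimulus_times = NULL, duration = 1,
                         latency = 0.5) {
  if (is.null(stimulus_times)) stimulus_times <- attr(trace, "events")
  det <- trace_detections(trace, attr(trace, "threshold") %||% 0.5)
  rng <- range(trace$time_s)
  hi <- 0.5 + duration + latency
  onsets <- stimulus_times[stimulus_times + hi <= rng[2] &
                           stimulus_times - duration >= rng[1]]
  miss_times <- trace$time_s[trace$missing]
  clean <- function(lo, hi) !any(miss_times >= lo & miss_times <= hi)
  labels <- integer(0); preds <- integer(0)
  used <- rep(FALSE, length(det))
  # attribute detections to *any* onset (also ones outside the scored range,
  # e.g. during warm-up margins) so event-caused crossings are never counted
  # as unattributed false positives
  for (on in stimulus_times) {
    used <- used | (det >= on + 0.5 & det <= on + hi) |
      (det >= on - duration & det < on)
  }
  for (on in onsets) {
    hit <- det >= on + 0.5 & det <= on + hi
    if (clean(on + 0.5, on + hi)) {
      labels <- c(labels, 1L); preds <- c(preds, as.integer(any(hit)))
    }
    neg_hit <- det >= on - duration & det < on
    if (clean(on - duration, on)) {
      labels <- c(labels, 0L); preds <- c(preds, as.integer(any(neg_hit)))
    }
  }
  extra <- sum(!used)
  labels <- c(labels, rep(0L, extra))
  preds <- c(preds, rep(1L, extra))
  out <- metric_report(labels, preds, model_name = "online")
  cc <- confusion(labels, preds)
  out$tp <- cc$tp; out$fp <- cc$fp; out$tn <- cc$tn; out$fn <- cc$fn
  attr(out, "detections") <- det
  out
}

#' Plot an online prediction trace
#'
#' Probability stream with the detection threshold and, when known, the true
#' stimulus onsets.
#'
#' @param object A `tepr_online_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tepr_online_trace
#' @export
autoplot.tepr_online_trace <- function(object, ...) {
  gg <- ggplot(object, aes(x = .data$time_s, y = .data$prob)) +
    geom_line(colour = "steelblue", na.rm = TRUE) +
    geom_hline(yintercept = attr(object, "threshold") %||% 0.5, linetype = "dashed") +
    labs(x = "time (s)", y = "event probability", title = "Online event detection") +
    theme_minimal()
  ev <- attr(object, "events")
  if (length(ev) > 0) {
    ev <- ev[ev >= min(object$time_s) & ev <= max(object$time_s)]
    gg <- gg + geom_vline(xintercept = ev, colour = "red", linetype = "dotted")
  }
  gg
}
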