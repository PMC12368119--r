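# Shared fixtures, built in code at test time.

small_cfg <- function(seed = 11, ...) {
  tepr_config(
    n_participants = 2, sessions_per_participant = 1,
    trials_per_session = c(DPT = 5, MA = 5, PVT = 5, VWM = 5),
    rest_duration = 30, seed = seed, ...
  )
}

# Linearly separable toy windows: class 1 carries a constant offset on the
# pupil channel.
toy_windows <- function(n = 24, n_time = 250, n_feat = 3, offset = 1, seed = 1) {
  set.seed(seed)
  X <- array(rnorm(n * n_time * n_feat), c(n, n_time, n_feat))
  y <- rep(0:1, length.out = n)
  X[, , 1] <- X[, , 1] + offset * y
  feats <- c("pupil", "gaze_x", "gaze_y")[seq_len(n_feat)]
  pupilevents:::new_windows(
    X,
    tibble::tibble(window_id = seq_len(n), participant_id = "P01",
                   session_id = "S01", task = "MA", label = as.integer(y),
                   anchor_time = 0, synthetic = FALSE),
    feats, 250
  )
}

# Random imbalanced window set with participant structure, for sampling and
# evaluation tests.
random_windows <- function(n0 = 30, n1 = 20, n_time = 40, n_feat = 3,
                           n_participants = 6, seed = 2) {
  set.seed(seed)
  n <- n0 + n1
  X <- array(rnorm(n * n_time * n_feat), c(n, n_time, n_feat))
  feats <- c("pupil", "gaze_x", "gaze_y")[seq_len(n_feat)]
  pupilevents:::new_windows(
    X,
    tibble::tibble(
      window_id = seq_len(n),
      participant_id = sprintf("P%02d", rep_len(seq_len(n_participants), n)),
      session_id = "S01", task = "MA",
      label = c(rep(0L, n0), rep(1L, n1)),
      anchor_time = 0, synthetic = FALSE
    ),
    feats, round(n_time)
  )
}

# Tiny fast model config for training-path tests.
tiny_config <- function(architecture = "MLP", n_time = 40, ...) {
  model_config(architecture, window_length = n_time, max_epochs = 5,
               patience = 5, batch_size = 16, seed = 1, ...)
}
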