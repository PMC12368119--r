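#' Per-session standardization
#'
#' Z-scores each feature (pupil diameter, gaze X, gaze Y) independently within
#' each recording, using that recording's own non-missing mean and standard
#' deviation, so that every session has mean 0 and sd 1 per feature. Each
#' session is treated as a separate entity even for repeat participants:
#' equipment calibration, lighting and state shift baselines between days, and
#' per-session scaling removes exactly that variation. Missing samples are
#' preserved in place.
#'
#' @param samples A samples tibble (columns `participant_id`, `session_id`,
#'   `task`, `time_s`, `pupil_mm`, `gaze_x`, `gaze_y`), a `tepr_recording`, or
#'   a `tepr_cohort`.
#' @return An object of the same shape with standardized feature columns.
#' @examples
#' rec <- generate_session(tepr_config(), "P01", "S01", "MA", seed = 1)
#' std <- standardize_sessions(rec)
#' mean(std$samples$pupil_mm, na.rm = TRUE)
#' @export
standardize_sessions <- function(samples) {
  if (inherits(samples, "tepr_recording") || inherits(samples, "tepr_cohort")) {
    out <- samples
    out$samples <- standardize_sessions(samples$samples)
    return(out)
  }
  feats <- c("pupil_mm", "gaze_x", "gaze_y")
  zscore <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2L) abort("cannot standardize: fewer than 2 non-missing samples in a session feature")
    s <- sd(v[ok])
    if (s == 0) abort("degenerate session: zero variance in a feature; cannot standardize")
    (v - mean(v[ok])) / s
  }
  samples |>
    group_by(.data$participant_id, .data$session_id, .data$task) |>
    mutate(across(dplyr::all_of(feats), zscore)) |>
    ungroup()
}

# Resolve one recording group into a values matrix + uniform time grid.
recording_groups <- function(samples) {
  samples |>
    group_by(.data$participant_id, .data$session_id, .data$task) |>
    dplyr::group_split()
}

feature_matrix <- function(g, features) {
  m <- as.matrix(g[, c("pupil_mm", "gaze_x", "gaze_y")])
  colnames(m) <- c("pupil", "gaze_x", "gaze_y")
  m[, features, drop = FALSE]
}

#' Extract labeled windows around stimulus onsets
#'
#' For every stimulus onset at time T, cuts two windows: one labeled 0
#' (event absent) ending at the onset, covering `[T - duration, T)`, and one
#' labeled 1 (event present) starting half a second after it, covering
#' `[T + 0.5, T + 0.5 + duration)`. The 0.5-s offset skips the initial
#' constriction phase and the saccadic gaze shift so the label-1 window
#' captures the cognitive dilation. Intervals are half-open with the sample at
#' the interval start included. Onsets whose windows would cross a recording
#' edge are skipped with a message.
#'
#' @param samples Standardized samples tibble (see [standardize_sessions()]).
#' @param events Events tibble with columns `participant_id`, `session_id`,
#'   `task`, `stimulus_time_s`.
#' @param duration Window duration in seconds (0.5, 1, 2 or 3 in the duration
#'   ablation; default 1).
#' @param features Feature columns to keep (default all three).
#' @return A `tepr_windows` set with one label-0 and one label-1 window per
#'   usable onset.
#' @export
extract_task_windows <- function(samples, events, duration = 1,
                                 features = c("pupil", "gaze_x", "gaze_y")) {
  groups <- recording_groups(filter(samples, .data$task != "REST"))
  sets <- purrr::map(groups, function(g) {
    key <- g[1, c("participant_id", "session_id", "task")]
    ev <- dplyr::semi_join(events, key,
                           by = c("participant_id", "session_id", "task"))
    extract_windows_one(g, ev$stimulus_time_s, duration, features)
  })
  sets <- sets[!purrr::map_lgl(sets, is.null)]
  if (length(sets) == 0L) abort("no extractable task windows")
  windows_bind(sets)
}

extract_windows_one <- function(g, onsets, duration, features) {
  if (length(onsets) == 0L) return(NULL)
  fs <- round(1 / median(diff(g$time_s)))
  n_per <- round(duration * fs)
  t0 <- g$time_s[1]
  n <- nrow(g)
  vals <- feature_matrix(g, features)

  starts0 <- round((onsets - duration - t0) * fs) + 1
  starts1 <- round((onsets + 0.5 - t0) * fs) + 1
  ok <- starts0 >= 1 & (starts1 + n_per - 1) <= n
  if (any(!ok)) {
    inform(sprintf("skipped %d onset(s) too close to a recording edge in %s/%s/%s",
                   sum(!ok), g$participant_id[1], g$session_id[1], g$task[1]))
  }
  anchors <- c(starts0[ok], starts1[ok])
  labels <- rep(c(0L, 1L), each = sum(ok))
  if (length(anchors) == 0L) return(NULL)

  X <- array(NA_real_, c(length(anchors), n_per, length(features)))
  for (i in seq_along(anchors)) {
    X[i, , ] <- vals[anchors[i] + seq_len(n_per) - 1, ]
  }
  meta <- tibble(
    window_id = seq_along(anchors),
    participant_id = g$participant_id[1], session_id = g$session_id[1],
    task = g$task[1], label = labels,
    anchor_time = t0 + (anchors - 1) / fs, synthetic = FALSE
  )
  new_windows(X, meta, features, fs)
}

#' Extract non-overlapping negative windows from REST data
#'
#' Randomly places up to `n_per_session` label-0 windows in each REST
#' recording. Placement is slotted: the recording is divided into contiguous
#' non-overlapping slots of one window length and a random subset of slots is
#' selected, which guarantees pairwise disjoint windows and makes the capacity
#' (total duration / window duration) exact. Asking for more windows than the
#' capacity returns the maximum placeable number with a message.
#'
#' @inheritParams extract_task_windows
#' @param n_per_session Number of windows to draw from each REST recording.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `tepr_windows` set of label-0 REST windows.
#' @export
extract_rest_windows <- function(samples, n_per_session, duration = 1,
                                 features = c("pupil", "gaze_x", "gaze_y"),
                                 seed = NULL) {
  groups <- recording_groups(filter(samples, .data$task == "REST"))
  if (length(groups) == 0L) abort("no REST recordings in `samples`")
  run <- function() {
    sets <- purrr::map(groups, function(g) {
      fs <- round(1 / median(diff(g$time_s)))
      n_per <- round(duration * fs)
      capacity <- floor(nrow(g) / n_per)
      k <- min(n_per_session, capacity)
      if (k < n_per_session) {
        inform(sprintf("REST %s/%s: capacity %d < requested %d windows",
                       g$participant_id[1], g$session_id[1], capacity, n_per_session))
      }
      if (k == 0L) return(NULL)
      slots <- sort(sample.int(capacity, k))
      anchors <- (slots - 1) * n_per + 1
      vals <- feature_matrix(g, features)
      X <- array(NA_real_, c(k, n_per, length(features)))
      for (i in seq_len(k)) X[i, , ] <- vals[anchors[i] + seq_len(n_per) - 1, ]
      meta <- tibble(
        window_id = seq_len(k),
        participant_id = g$participant_id[1], session_id = g$session_id[1],
        task = "REST", label = 0L,
        anchor_time = g$time_s[1] + (anchors - 1) / fs, synthetic = FALSE
      )
      new_windows(X, meta, features, fs)
    })
    sets <- sets[!purrr::map_lgl(sets, is.null)]
    if (length(sets) == 0L) abort("REST recordings too short for any window")
    windows_bind(sets)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Remove windows containing missing samples
#'
#' Drops every window with at least one missing value in any feature and
#' reports how many were removed (attribute `"n_dropped"`).
#'
#' @param w A `tepr_windows` object.
#' @return The filtered `tepr_windows`, with attribute `n_dropped`.
#' @export
filter_missing <- function(w) {
  keep <- !apply(is.na(w$X), 1, any)
  dropped <- sum(!keep)
  if (dropped > 0) inform(sprintf("filter_missing: dropped %d of %d windows", dropped, length(keep)))
  out <- windows_subset(w, keep)
  attr(out, "n_dropped") <- dropped
  out
}

#' SMOTE rebalancing of a training window set
#'
#' Augments the minority class with synthetic windows until the two classes
#' are equally populated (Synthetic Minority Oversampling Technique). Each
#' synthetic window is a random convex combination `a + lambda * (b - a)`,
#' `lambda ~ U(0, 1)`, of a minority window `a` and one of its `k_neighbors`
#' nearest minority neighbours `b`, with distances computed on the flattened
#' (time x feature) vectors; the result is reshaped back to window geometry.
#' Original windows are untouched; synthetic ones carry `synthetic = TRUE` in
#' the metadata. Apply to training data only — test data must stay untouched.
#'
#' @param w A `tepr_windows` object containing both classes.
#' @param k_neighbors Number of nearest minority neighbours to interpolate
#'   toward (reduced with a message if the minority class is smaller).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `tepr_windows` object with equal class counts.
#' @export
smote_rebalance <- function(w, k_neighbors = 5, seed = NULL) {
  labs <- w$meta$label
  n1 <- sum(labs == 1L); n0 <- sum(labs == 0L)
  if (n1 == 0L || n0 == 0L) abort("SMOTE requires both classes in the input")
  if (n1 == n0) return(w)
  minority <- if (n1 < n0) 1L else 0L
  n_min <- min(n1, n0); n_need <- abs(n1 - n0)
  if (n_min < 2L) abort("SMOTE requires at least 2 minority windows")
  k <- k_neighbors
  if (n_min - 1L < k) {
    k <- n_min - 1L
    inform(sprintf("smote_rebalance: minority count %d <= k; using k = %d", n_min, k))
  }
  run <- function() {
    idx_min <- which(labs == minority)
    d <- dim(w$X)
    flat <- matrix(w$X[idx_min, , , drop = FALSE], nrow = n_min)
    # k nearest minority neighbours by Euclidean distance on flattened vectors
    dm <- as.matrix(stats::dist(flat))
    diag(dm) <- Inf
    nn <- t(apply(dm, 1, function(r) order(r)[seq_len(k)]))
    base_i <- rep_len(seq_len(n_min), n_need)
    nbr_i <- nn[cbind(base_i, sample.int(k, n_need, replace = TRUE))]
    lam <- runif(n_need)
    synth_flat <- flat[base_i, , drop = FALSE] +
      lam * (flat[nbr_i, , drop = FALSE] - flat[base_i, , drop = FALSE])
    Xs <- array(synth_flat, c(n_need, d[2], d[3]))
    meta_s <- w$meta[idx_min[base_i], ]
    meta_s$synthetic <- TRUE
    synth <- new_windows(Xs, meta_s, w$features, w$sampling_rate)
    windows_bind(list(w, synth))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Participant-level fold assignment
#'
#' Randomly partitions participants into `n_folds` folds whose sizes differ by
#' at most one (57 participants over 5 folds give sizes 12/12/11/11/11).
#' Splitting at the participant level — never at the session or sample
#' level — prevents leakage of a participant's data across train/test.
#'
#' @param participant_ids Character vector of unique participant identifiers.
#' @param n_folds Number of folds.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `participant_id`, `fold`.
#' @export
make_folds <- function(participant_ids, n_folds = 5, seed = NULL) {
  participant_ids <- unique(participant_ids)
  if (n_folds > length(participant_ids)) {
    abort("`n_folds` exceeds the number of participants")
  }
  run <- function() {
    shuffled <- sample(participant_ids)
    tibble(participant_id = shuffled,
           fold = rep_len(seq_len(n_folds), length(shuffled))) |>
      arrange(.data$participant_id)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Assemble leak-free train/validation/test window sets
#'
#' Splits a window set by participant fold: the `test_fold` participants form
#' the test set, the `val_fold` participants the validation set, and everyone
#' else the training set. SMOTE rebalancing is applied to the training set
#' only; validation and test sets keep their natural class imbalance. The
#' three participant sets are verified pairwise disjoint.
#'
#' @param w A `tepr_windows` object.
#' @param folds Fold assignment from [make_folds()].
#' @param test_fold,val_fold Distinct fold indices.
#' @param smote Apply SMOTE to the training set?
#' @param k_neighbors Passed to [smote_rebalance()].
#' @param seed Integer seed for SMOTE; `NULL` uses the current RNG state.
#' @return A list with `tepr_windows` elements `train`, `val`, `test`.
#' @export
assemble_split <- function(w, folds, test_fold, val_fold,
                           smote = TRUE, k_neighbors = 5, seed = NULL) {
  if (test_fold == val_fold) abort("`test_fold` and `val_fold` must differ")
  fold_of <- setNames(folds$fold, folds$participant_id)
  wf <- fold_of[w$meta$participant_id]
  if (anyNA(wf)) abort("some windows belong to participants missing from `folds`")
  sets <- list(
    train = windows_subset(w, !wf %in% c(test_fold, val_fold)),
    val = windows_subset(w, wf == val_fold),
    test = windows_subset(w, wf == test_fold)
  )
  parts <- purrr::map(sets, ~ unique(.x$meta$participant_id))
  if (length(intersect(parts$train, parts$test)) > 0 ||
      length(intersect(parts$train, parts$val)) > 0 ||
      length(intersect(parts$val, parts$test)) > 0) {
    abort("participant leakage detected across train/val/test")
  }
  if (smote) sets$train <- smote_rebalance(sets$train, k_neighbors, seed = seed)
  sets
}

#' Full preprocessing: cohort to labeled windows
#'
#' Standardizes every recording, extracts the paired onset windows from the
#' task recordings and random non-overlapping negatives from REST, and drops
#' windows containing missing samples. The number of REST windows per session
#' defaults to half the session's onset count, which yields an overall
#' event-present prevalence of 40%.
#'
#' @param cohort A `tepr_cohort`.
#' @param duration Window duration in seconds.
#' @param rest_windows_per_session REST negatives per session; `NULL` for the
#'   40%-prevalence default.
#' @param features Feature columns to keep.
#' @param seed Integer seed for REST window placement.
#' @return A filtered `tepr_windows` set.
#' @export
make_windows <- function(cohort, duration = 1, rest_windows_per_session = NULL,
                         features = c("pupil", "gaze_x", "gaze_y"), seed = NULL) {
  std <- standardize_sessions(cohort$samples)
  if (is.null(rest_windows_per_session)) {
    per_session <- cohort$events |>
      dplyr::count(.data$participant_id, .data$session_id) |>
      pull(.data$n)
    rest_windows_per_session <- max(1L, round(mean(per_session) * 0.5))
  }
  task_w <- extract_task_windows(std, cohort$events, duration, features)
  rest_w <- extract_rest_windows(std, rest_windows_per_session, duration,
                                 features, seed = seed)
  filter_missing(windows_bind(list(task_w, rest_w)))
}
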