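test_that("per-session standardization zeroes mean and unit-scales sd", {
  rec <- generate_session(small_cfg(), "P01", "S01", "MA", seed = 3)
  std <- standardize_sessions(rec)
  for (col in c("pupil_mm", "gaze_x", "gaze_y")) {
    v <- std$samples[[col]]
    expect_lt(abs(mean(v, na.rm = TRUE)), 1e-9)
    expect_lt(abs(sd(v, na.rm = TRUE) - 1), 1e-9)
  }
  # missing markers stay in place
  expect_identical(is.na(std$samples$pupil_mm), is.na(rec$samples$pupil_mm))

  # idempotent up to floating tolerance
  std2 <- standardize_sessions(std)
  expect_equal(std2$samples$pupil_mm, std$samples$pupil_mm, tolerance = 1e-12)

  # two sessions differing only in baseline standardize identically
  r1 <- generate_session(small_cfg(), "P01", "S01", "MA", seed = 21, baseline = 3.6)
  r2 <- generate_session(small_cfg(), "P01", "S02", "MA", seed = 21, baseline = 4.4)
  s1 <- standardize_sessions(r1)$samples$pupil_mm
  s2 <- standardize_sessions(r2)$samples$pupil_mm
  expect_equal(s1, s2, tolerance = 1e-9)

  # zero-variance feature is a hard error
  bad <- r1$samples
  bad$gaze_x <- 500
  expect_error(standardize_sessions(bad), "variance")
})

test_that("task windows pair each onset with one 0 and one 1 window", {
  cfg <- tepr_config(n_participants = 1, missing_rate = 0)
  rec <- generate_session(cfg, "P01", "S01", "DPT", seed = 5)
  std <- standardize_sessions(rec)
  w <- extract_task_windows(std$samples, rec$events)

  expect_equal(n_windows(w), 320)  # two windows per onset
  expect_equal(sum(w$meta$label == 0), 160)
  expect_equal(sum(w$meta$label == 1), 160)
  expect_equal(dim(w$X)[2], 250)   # 1 s at 250 Hz

  # geometry: label-1 window starts exactly onset + 0.5 s (within half a
  # sample); label-0 window ends at the onset
  on <- sort(rec$events$stimulus_time_s)
  a1 <- sort(w$meta$anchor_time[w$meta$label == 1])
  a0 <- sort(w$meta$anchor_time[w$meta$label == 0])
  expect_true(all(abs(a1 - (on + 0.5)) <= 0.5 / 250 + 1e-9))
  expect_true(all(abs((a0 + 1) - on) <= 0.5 / 250 + 1e-9))

  # the two windows of one onset share no samples: gap of 0.5 s
  expect_true(all(a1 - (a0 + 1) > 0.49))
})

test_that("duration ablation keeps the labeling geometry", {
  cfg <- tepr_config(n_participants = 1, missing_rate = 0)
  rec <- generate_session(cfg, "P01", "S01", "MA", seed = 6)
  std <- standardize_sessions(rec)
  for (dur in c(0.5, 2)) {
    w <- extract_task_windows(std$samples, rec$events, duration = dur)
    expect_equal(dim(w$X)[2], round(dur * 250))
    # onsets too close to an edge are skipped, so match each window
    # anchor to its nearest onset
    on <- rec$events$stimulus_time_s
    a1 <- w$meta$anchor_time[w$meta$label == 1]
    a0 <- w$meta$anchor_time[w$meta$label == 0]
    d1 <- vapply(a1, function(a) min(abs(a - (on + 0.5))), numeric(1))
    d0 <- vapply(a0, function(a) min(abs(a + dur - on)), numeric(1))
    expect_true(all(d1 <= 0.5 / 250 + 1e-9))
    expect_true(all(d0 <= 0.5 / 250 + 1e-9))
  }
})

test_that("REST windows are non-overlapping, capacity-limited, reproducible", {
  cfg <- tepr_config(n_participants = 1, missing_rate = 0, rest_duration = 10)
  rec <- generate_session(cfg, "P01", "S01", "REST", seed = 2)
  std <- standardize_sessions(rec)

  # pigeonhole: 10 s holds at most 10 one-second windows
  expect_message(
    w <- extract_rest_windows(std$samples, n_per_session = 11, seed = 1),
    "capacity"
  )
  expect_lte(n_windows(w), 10)
  expect_true(all(w$meta$label == 0))

  # pairwise disjoint
  a <- sort(w$meta$anchor_time)
  expect_true(all(diff(a) >= 1 - 1e-9))

  # seeded determinism
  w2 <- extract_rest_windows(std$samples, n_per_session = 11, seed = 1)
  expect_identical(w$meta$anchor_time, w2$meta$anchor_time)

  # a 360-s REST easily hosts 100
  cfg2 <- tepr_config(n_participants = 1, missing_rate = 0)
  rec2 <- standardize_sessions(generate_session(cfg2, "P01", "S01", "REST", seed = 3))
  w3 <- extract_rest_windows(rec2$samples, n_per_session = 100, seed = 1)
  expect_equal(n_windows(w3), 100)
})

test_that("filter_missing drops exactly the windows an independent scan finds", {
  w <- random_windows(n0 = 25, n1 = 15, seed = 3)
  # plant missing values into a known subset
  set.seed(4)
  bad <- sample(n_windows(w), 7)
  for (i in bad) w$X[i, sample(40, 1), sample(3, 1)] <- NA

  # independent per-window scan oracle
  oracle_bad <- vapply(seq_len(n_windows(w)),
                       function(i) anyNA(w$X[i, , ]), logical(1))
  expect_equal(sort(which(oracle_bad)), sort(bad))

  expect_message(f <- filter_missing(w), "dropped")
  expect_equal(n_windows(f), n_windows(w) - length(bad))
  expect_equal(attr(f, "n_dropped"), length(bad))
  expect_false(anyNA(f$X))

  # identity on clean input
  clean <- random_windows(seed = 5)
  expect_identical(filter_missing(clean)$X, clean$X)
})

test_that("SMOTE balances classes with convex synthetic windows", {
  w <- random_windows(n0 = 30, n1 = 20, seed = 7)
  out <- smote_rebalance(w, k_neighbors = 5, seed = 1)
  expect_equal(sum(out$meta$label == 0), sum(out$meta$label == 1))
  # originals untouched, synthetics flagged
  expect_identical(out$X[seq_len(n_windows(w)), , ], w$X)
  expect_equal(sum(out$meta$synthetic), 10)

  # geometric oracle: every synthetic flattened vector lies on a segment
  # between two minority windows (residual of the best projection ~ 0)
  minor <- which(w$meta$label == 1)
  flat <- matrix(w$X[minor, , ], length(minor))
  synth <- matrix(out$X[out$meta$synthetic, , ], sum(out$meta$synthetic))
  for (si in seq_len(nrow(synth))) {
    v <- synth[si, ]
    best <- Inf
    for (a in seq_len(nrow(flat))) for (b in seq_len(nrow(flat))) {
      if (a == b) next
      d <- flat[b, ] - flat[a, ]
      lam <- sum((v - flat[a, ]) * d) / sum(d * d)
      if (lam < -1e-9 || lam > 1 + 1e-9) next
      best <- min(best, sqrt(sum((flat[a, ] + lam * d - v)^2)))
    }
    expect_lt(best, 1e-9)
  }

  # balanced input returned unchanged
  bal <- random_windows(n0 = 20, n1 = 20, seed = 8)
  expect_identical(smote_rebalance(bal, seed = 1)$X, bal$X)

  # k reduced with a message when the minority class is tiny
  small <- random_windows(n0 = 12, n1 = 4, seed = 9)
  expect_message(smote_rebalance(small, k_neighbors = 5, seed = 1), "using k")

  # minority of one is rejected
  one <- random_windows(n0 = 8, n1 = 1, seed = 10)
  expect_error(smote_rebalance(one, seed = 1), "at least 2")
})

test_that("participant folds partition evenly and splits never leak", {
  ids57 <- sprintf("P%02d", 1:57)
  f <- make_folds(ids57, 5, seed = 3)
  sizes <- sort(as.integer(table(f$fold)), decreasing = TRUE)
  expect_equal(sizes, c(12, 12, 11, 11, 11))
  expect_setequal(f$participant_id, ids57)

  f10 <- make_folds(sprintf("P%02d", 1:10), 5, seed = 3)
  expect_true(all(table(f10$fold) == 2))
  expect_error(make_folds(sprintf("P%02d", 1:3), 5), "exceeds")

  w <- random_windows(n0 = 40, n1 = 30, n_participants = 10, seed = 11)
  folds <- make_folds(unique(w$meta$participant_id), 5, seed = 1)
  sp <- assemble_split(w, folds, test_fold = 1, val_fold = 2, seed = 1)
  parts <- lapply(sp, function(s) unique(s$meta$participant_id))
  expect_length(intersect(parts$train, parts$test), 0)
  expect_length(intersect(parts$train, parts$val), 0)
  expect_length(intersect(parts$val, parts$test), 0)

  # SMOTE on train only: test/val class counts match the raw split
  raw <- assemble_split(w, folds, 1, 2, smote = FALSE)
  expect_equal(table(sp$test$meta$label), table(raw$test$meta$label))
  expect_equal(table(sp$val$meta$label), table(raw$val$meta$label))
  expect_equal(sum(sp$train$meta$label == 0), sum(sp$train$meta$label == 1))
  expect_false(any(sp$test$meta$synthetic))

  expect_error(assemble_split(w, folds, 1, 1), "differ")
})

test_that("end-to-end window counts reconcile with an independent counter", {
  cfg <- small_cfg(seed = 31)
  cfg$missing_rate <- 0
  coh <- suppressWarnings(generate_cohort(cfg))
  w <- make_windows(coh, rest_windows_per_session = 4, seed = 1)
  # no missing data: 2 windows per onset + the REST windows placed
  expected <- 2 * nrow(coh$events) +
    4 * nrow(dplyr::distinct(coh$events, participant_id, session_id))
  expect_equal(n_windows(w), expected)
})

test_that("window sets round-trip through the text serialization", {
  w <- random_windows(n0 = 6, n1 = 4, n_time = 10, seed = 12)
  dir <- withr::local_tempdir()
  write_windows(w, dir)
  back <- read_windows(dir)
  expect_equal(back$X, w$X, tolerance = 1e-12)
  expect_equal(back$meta$label, w$meta$label)
  expect_equal(back$features, w$features)
})

test_that("pupil-only ablation drops the gaze channels", {
  w <- random_windows(seed = 13)
  p <- select_features(w, "pupil")
  expect_equal(dim(p$X)[3], 1)
  expect_equal(p$X[, , 1], w$X[, , 1])
  expect_error(select_features(w, "blink"), "unknown")
})
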