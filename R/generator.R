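#' Task-evoked pupil response kernel
#'
#' Noise-free pupil-diameter deviation (mm) at time `t_rel` relative to a
#' stimulus onset. The kernel is the sum of two smooth lobes: a gamma-shaped
#' constriction trough peaking at `constriction_duration` and a delayed
#' sigmoidal dilation ramp that plateaus near `dilation_amplitude` after about
#' one second. Task differences enter only through the constriction amplitude:
#' MA and VWM carry the base depth, PVT a much shallower dip, and DPT the base
#' depth plus a strong pupillary-light-reflex component followed by
#' re-dilation. REST carries no stimulus-locked response. The response is
#' strictly causal: zero for all `t_rel < 0`.
#'
#' @param t_rel Numeric vector of times (s) relative to the stimulus onset.
#' @param task One of `"DPT"`, `"MA"`, `"PVT"`, `"VWM"`, `"REST"`.
#' @param cfg A [tepr_config()].
#' @return Numeric vector of pupil-diameter deviations in mm.
#' @examples
#' cfg <- tepr_config()
#' pupil_response_kernel(c(-0.5, 0.6, 1.0), "MA", cfg)
#' @export
pupil_response_kernel <- function(t_rel, task, cfg = tepr_config()) {
  assert_task(task)
  if (task == "REST") return(numeric(length(t_rel)))
  a_con <- switch(task,
    DPT = cfg$constriction_amplitude + cfg$plr_amplitude_dpt,
    MA = cfg$constriction_amplitude,
    VWM = cfg$constriction_amplitude,
    PVT = 0.3 * cfg$constriction_amplitude
  )
  dil <- dilation_ramp(t_rel) * cfg$dilation_amplitude
  con <- gamma_lobe(t_rel, peak = cfg$constriction_duration, shape = 18) * a_con
  out <- dil - con
  out[t_rel < 0] <- 0
  out
}

# Unit-peak gamma-shaped lobe, zero at t <= 0, maximum 1 at t = peak.
gamma_lobe <- function(t, peak, shape) {
  theta <- peak / shape
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- (tp / peak)^shape * exp(shape - tp / theta)
  out
}

# Smooth dilation ramp: starts after ~0.3 s, near its maximum at 1 s, then
# returns toward baseline over the following seconds (the response is
# transient, not a sustained shift).
dilation_ramp <- function(t) {
  s <- pmax(t - 0.3, 0)
  s^2 / (s^2 + 0.3^2) * stats::plogis((2 - t) / 0.35)
}

#' Per-trial gaze trajectory
#'
#' Deterministic-in-shape, random-in-parameters gaze deviation for one trial,
#' evaluated at times `t_rel` relative to the stimulus onset. MA and PVT
#' trials show a saccadic step of magnitude about `gaze_step_sd` that
#' completes inside `saccade_window`; DPT trials show no stimulus-locked gaze
#' shift; VWM trials draw one of four gaze programs (single saccade to a
#' random target, two-step scan, smooth sweep, or hold) reflecting the varied
#' layouts of the memory arrays. The deviation fades back to fixation by
#' about 3 s. Trial-level randomness (step direction, magnitude, VWM program)
#' is drawn from the current RNG once per call; seed the RNG for
#' reproducibility. Fixation jitter is *not* included here — it is added by
#' [generate_session()].
#'
#' @inheritParams pupil_response_kernel
#' @return A tibble with columns `dx`, `dy`: gaze deviation in screen units.
#' @examples
#' set.seed(1)
#' gaze_trajectory(seq(-0.2, 1, by = 0.2), "MA", tepr_config())
#' @export
gaze_trajectory <- function(t_rel, task, cfg = tepr_config()) {
  assert_task(task)
  zero <- tibble(dx = numeric(length(t_rel)), dy = numeric(length(t_rel)))
  if (task %in% c("REST", "DPT")) return(zero)

  mid <- mean(cfg$saccade_window)
  rise <- (cfg$saccade_window[2] - cfg$saccade_window[1]) / 10
  step <- function(t, at = mid, width = rise) {
    stats::plogis((t - at) / width) * (t > 0)
  }
  fade <- function(t) 1 - stats::plogis((t - 2.5) / 0.15)
  mag <- function(base) base * pmax(rnorm(1, 1, 0.15), 0.2)

  if (task %in% c("MA", "PVT")) {
    sx <- sample(c(-1, 1), 1)
    sy <- sample(c(-1, 1), 1)
    s <- step(t_rel) * fade(t_rel)
    return(tibble(dx = sx * mag(cfg$gaze_step_sd[["x"]]) * s,
                  dy = sy * mag(cfg$gaze_step_sd[["y"]]) * s))
  }

  # VWM: several distinct per-trial gaze programs.
  program <- sample(c("saccade", "two_step", "sweep", "hold"), 1,
                    prob = c(0.3, 0.3, 0.2, 0.2))
  ang <- runif(1, 0, 2 * pi)
  mx <- mag(cfg$gaze_step_sd[["x"]])
  my <- mag(cfg$gaze_step_sd[["y"]])
  f <- fade(t_rel)
  switch(program,
    saccade = {
      s <- step(t_rel) * f
      tibble(dx = cos(ang) * mx * s, dy = sin(ang) * my * s)
    },
    two_step = {
      ang2 <- runif(1, 0, 2 * pi)
      s1 <- step(t_rel) * f
      s2 <- step(t_rel, at = 0.8, width = 0.05) * f
      tibble(dx = (cos(ang) * s1 + (cos(ang2) - cos(ang)) * s2) * mx,
             dy = (sin(ang) * s1 + (sin(ang2) - sin(ang)) * s2) * my)
    },
    sweep = {
      env <- step(t_rel) * f
      tibble(dx = mx * sin(2 * pi * 0.8 * pmax(t_rel, 0) + ang) * env,
             dy = my * cos(2 * pi * 0.8 * pmax(t_rel, 0) + ang) * env)
    },
    hold = zero
  )
}

#' Generate one synchronized recording
#'
#' Assembles a single participant-session recording of one task (or REST):
#' uniformly sampled pupil diameter, gaze X/Y on the 0--1000 screen coordinate
#' system ((0,0) top-left), and the ground-truth stimulus onset times. The
#' pupil series is baseline + stimulus-locked kernels + slow drift + white
#' noise; gaze is fixation centre + autoregressive jitter + per-trial
#' trajectories; tracking dropouts are contiguous `NA` runs at rate
#' `missing_rate`. Consecutive onsets are separated by more than 3 s, so
#' pre-onset and post-onset windows of distinct trials never overlap.
#'
#' @inheritParams pupil_response_kernel
#' @param participant_id,session_id Identifiers stored with every sample.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param baseline Pupil baseline in mm; drawn from
#'   `cfg$baseline_pupil_range` when `NULL`.
#' @param duration Optional fixed session duration (s). The default sizes the
#'   session to its trials; an explicit duration too short to host the
#'   requested trials is an error.
#' @return A `tepr_recording`: list with `samples` (tibble: `participant_id`,
#'   `session_id`, `task`, `time_s`, `pupil_mm`, `gaze_x`, `gaze_y`) and
#'   `events` (tibble: `participant_id`, `session_id`, `task`,
#'   `stimulus_time_s`).
#' @examples
#' rec <- generate_session(tepr_config(), "P01", "S01", "MA", seed = 7)
#' nrow(rec$events)
#' @export
generate_session <- function(cfg, participant_id, session_id, task,
                             seed = NULL, baseline = NULL, duration = NULL) {
  assert_task(task)
  validate_tepr_config(cfg)
  run <- function() {
    generate_session_impl(cfg, participant_id, session_id, task, baseline, duration)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

generate_session_impl <- function(cfg, participant_id, session_id, task,
                                  baseline, duration) {
  fs <- cfg$sampling_rate
  if (task == "REST") {
    onsets <- numeric(0)
    dur <- cfg$rest_duration
  } else {
    n_tr <- cfg$trials_per_session[[task]]
    gaps <- runif(n_tr - 1, cfg$inter_trial_interval[1], cfg$inter_trial_interval[2])
    onsets <- 2 + c(0, cumsum(gaps))
    dur <- if (is.null(duration)) max(onsets) + 2 else duration
    if (max(onsets) + 1.5 > dur) {
      abort(sprintf(
        "session too short: %d %s trials at the configured inter-trial interval need >= %.1f s, got %.1f s",
        n_tr, task, max(onsets) + 1.5, dur))
    }
  }
  n <- ceiling(dur * fs)
  t <- (seq_len(n) - 1) / fs

  if (is.null(baseline)) {
    baseline <- runif(1, cfg$baseline_pupil_range[1], cfg$baseline_pupil_range[2])
  }
  pupil <- rep(baseline, n) + session_drift(n, fs) + rnorm(n, 0, cfg$noise_sd)
  gx <- rep(500, n) + fixation_jitter(n)
  gy <- rep(500, n) + fixation_jitter(n)

  for (on in onsets) {
    idx <- which(t >= on & t <= on + 5)
    tr <- t[idx] - on
    pupil[idx] <- pupil[idx] + pupil_response_kernel(tr, task, cfg)
    g <- gaze_trajectory(tr, task, cfg)
    gx[idx] <- gx[idx] + g$dx
    gy[idx] <- gy[idx] + g$dy
  }

  miss <- missing_mask(n, fs, cfg$missing_rate)
  pupil[miss] <- NA_real_
  gx[miss] <- NA_real_
  gy[miss] <- NA_real_

  samples <- tibble(
    participant_id = participant_id, session_id = session_id, task = task,
    time_s = t, pupil_mm = pupil, gaze_x = gx, gaze_y = gy
  )
  events <- tibble(
    participant_id = participant_id, session_id = session_id, task = task,
    stimulus_time_s = onsets
  )
  structure(list(samples = samples, events = events, sampling_rate = fs),
            class = "tepr_recording")
}

# Slow baseline drift: spline through sparse random knots, |drift| <= 0.2 mm.
session_drift <- function(n, fs) {
  dur <- n / fs
  k <- max(4, ceiling(dur / 30))
  knots <- cumsum(rnorm(k, 0, 0.05))
  knots <- knots - mean(knots)
  peak <- max(abs(knots), 1e-12)
  if (peak > 0.2) knots <- knots * 0.2 / peak
  stats::spline(x = seq(0, dur, length.out = k), y = knots, xout = (seq_len(n) - 1) / fs)$y
}

# AR(1) fixation jitter, stationary sd ~3 screen units.
fixation_jitter <- function(n, rho = 0.97, sd_stat = 3) {
  e <- rnorm(n, 0, sd_stat * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

# Contiguous dropout runs (mean 0.2 s), stratified so runs never overlap.
missing_mask <- function(n, fs, rate) {
  miss <- logical(n)
  if (rate <= 0) return(miss)
  run_mean <- round(0.2 * fs)
  n_runs <- max(1, round(n * rate / run_mean))
  block <- floor(n / n_runs)
  for (i in seq_len(n_runs)) {
    len <- max(1, round(rnorm(1, run_mean, run_mean / 5)))
    lo <- (i - 1) * block + 1
    start <- lo + sample.int(max(block - len, 1), 1) - 1
    miss[start:min(start + len - 1, i * block, n)] <- TRUE
  }
  miss
}

#' Sample per-participant session counts
#'
#' Draws how many sessions each participant completed: rounded draws from a
#' normal distribution with mean 6 and sd 3.33, clamped to 1--10, matching a
#' protocol where participants returned for up to 10 sessions with a median
#' of 6.
#'
#' @param n Number of participants.
#' @return Integer vector of length `n` with values in 1--10.
#' @examples
#' set.seed(1)
#' median(sample_session_counts(57))
#' @export
sample_session_counts <- function(n) {
  pmin(pmax(round(rnorm(n, 6, 3.33)), 1L), 10L)
}

#' Generate a multi-participant cohort
#'
#' Generates every recording of a cohort: for each participant, a number of
#' sessions (fixed by `cfg$sessions_per_participant`, or drawn by
#' [sample_session_counts()]), each session holding one REST recording and one
#' recording per cognitive task. Participants have individual baseline pupil
#' diameters, perturbed per session (so standardization has real work to do).
#' All randomness derives from `cfg$seed`: the same config gives bit-identical
#' cohorts.
#'
#' @param cfg A [tepr_config()].
#' @return A `tepr_cohort`: list with `samples` and `events` tibbles pooled
#'   over all recordings, plus the `config`.
#' @examples
#' coh <- generate_cohort(tepr_config(
#'   n_participants = 2, sessions_per_participant = 1,
#'   trials_per_session = c(DPT = 3, MA = 3, PVT = 3, VWM = 3),
#'   rest_duration = 20
#' ))
#' dplyr::count(coh$events, task)
#' @export
generate_cohort <- function(cfg) {
  validate_tepr_config(cfg)
  if (cfg$n_participants < 5) {
    warn("fewer than 5 participants: five-fold participant-level splitting will not be possible.")
  }
  plan <- with_seed(cfg$seed, {
    pids <- sprintf("P%02d", seq_len(cfg$n_participants))
    counts <- if (is.null(cfg$sessions_per_participant)) {
      sample_session_counts(cfg$n_participants)
    } else {
      rep(cfg$sessions_per_participant, cfg$n_participants)
    }
    baselines <- runif(cfg$n_participants,
                       cfg$baseline_pupil_range[1], cfg$baseline_pupil_range[2])
    tibble(participant_id = pids, n_sessions = counts, baseline = baselines)
  })

  recs <- purrr::pmap(plan, function(participant_id, n_sessions, baseline) {
    purrr::map(seq_len(n_sessions), function(s) {
      sid <- sprintf("S%02d", s)
      shift <- with_seed(derive_seed(cfg$seed, paste(participant_id, sid, "shift")),
                         rnorm(1, 0, 0.15))
      purrr::map(ALL_TASKS, function(task) {
        generate_session(
          cfg, participant_id, sid, task,
          seed = derive_seed(cfg$seed, paste(participant_id, sid, task)),
          baseline = baseline + shift
        )
      })
    })
  })
  recs <- purrr::list_flatten(purrr::list_flatten(recs))
  structure(
    list(
      samples = purrr::list_rbind(purrr::map(recs, "samples")),
      events = purrr::list_rbind(purrr::map(recs, "events")),
      config = cfg
    ),
    class = "tepr_cohort"
  )
}

#' @export
print.tepr_cohort <- function(x, ...) {
  cat("<tepr_cohort>", dplyr::n_distinct(x$samples$participant_id), "participants,",
      nrow(dplyr::distinct(x$samples, .data$participant_id, .data$session_id, .data$task)),
      "recordings,", nrow(x$events), "stimulus onsets\n")
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' Serializes a cohort to two CSV files, `recordings.csv` (one row per sample;
#' missing samples as empty fields) and `events.csv` (one row per stimulus
#' onset), and reads them back.
#'
#' @param cohort A `tepr_cohort` (or any list with `samples`/`events` tibbles).
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()` returns the directory invisibly; `read_cohort()`
#'   returns a `tepr_cohort` (without a config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$samples, file.path(dir, "recordings.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  samples <- as_tibble(utils::read.csv(file.path(dir, "recordings.csv"),
                                       na.strings = "", stringsAsFactors = FALSE))
  events <- as_tibble(utils::read.csv(file.path(dir, "events.csv"),
                                      na.strings = "", stringsAsFactors = FALSE))
  structure(list(samples = samples, events = events, config = NULL),
            class = "tepr_cohort")
}
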