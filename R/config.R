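#' Configuration for the synthetic TEPR generator
#'
#' Bundles every knob of the synthetic task-evoked pupillary response (TEPR)
#' generator. Defaults reproduce the study conditions the pipeline is designed
#' for: 250 Hz recordings, median pupil diameter between 3.5 and 4.5 mm, a
#' cognitive dilation of a few tenths of a millimetre that develops after
#' roughly half a second, an initial constriction lasting about 0.6 s (strongly
#' amplified in the Dot Probe Task by the pupillary light reflex), saccadic
#' gaze shifts in the first half second of MA/PVT trials, and per-session trial
#' counts of 160 (DPT), 40 (MA), 77 (PVT) and 48 (VWM) plus a 6-minute rest
#' recording.
#'
#' @param n_participants Number of participants in a cohort.
#' @param sessions_per_participant Fixed number of sessions per participant, or
#'   `NULL` to draw per-participant counts from a sampler whose median is about
#'   6 sessions, capped at 10 (see [sample_session_counts()]).
#' @param sampling_rate Sampling rate in Hz.
#' @param trials_per_session Named integer vector of stimulus (trial) counts
#'   per session for the four tasks.
#' @param rest_duration Duration of the rest recording in seconds.
#' @param baseline_pupil_range Two-element numeric, the mm interval participant
#'   baseline pupil diameters are drawn from.
#' @param dilation_amplitude Asymptotic cognitive dilation in mm.
#' @param constriction_amplitude Base depth of the initial constriction in mm
#'   (applies to MA/VWM; PVT shows 30% of it, DPT adds `plr_amplitude_dpt`).
#' @param constriction_duration Time of maximal constriction in seconds.
#' @param plr_amplitude_dpt Extra constriction depth in mm contributed by the
#'   pupillary light reflex in the DPT task.
#' @param saccade_window Two-element numeric, the post-onset interval (s)
#'   within which MA/PVT saccades complete.
#' @param gaze_step_sd Named numeric `c(x = , y = )`, typical saccade step
#'   magnitude in screen units (0--1000 coordinate system).
#' @param inter_trial_interval Two-element numeric, uniform bounds (s) for
#'   the gap between consecutive stimulus onsets; lower bound must exceed 3 s
#'   so the pre-onset and post-onset windows of neighbouring trials never
#'   interleave.
#' @param missing_rate Fraction of samples lost to tracking dropouts, in
#'   `[0, 0.2]`. Dropouts occur in contiguous runs of mean length 0.2 s.
#' @param noise_sd Standard deviation (mm) of white measurement noise on the
#'   pupil series.
#' @param seed Integer seed controlling all randomness in cohort generation.
#'
#' @return A `tepr_config` list.
#' @examples
#' cfg <- tepr_config(n_participants = 2, sessions_per_participant = 1)
#' cfg$trials_per_session
#' @export
tepr_config <- function(n_participants = 57,
                        sessions_per_participant = NULL,
                        sampling_rate = 250,
                        trials_per_session = c(DPT = 160, MA = 40, PVT = 77, VWM = 48),
                        rest_duration = 360,
                        baseline_pupil_range = c(3.5, 4.5),
                        dilation_amplitude = 0.2,
                        constriction_amplitude = 0.25,
                        constriction_duration = 0.6,
                        plr_amplitude_dpt = 0.8,
                        saccade_window = c(0, 0.5),
                        gaze_step_sd = c(x = 77, y = 60),
                        inter_trial_interval = c(3.2, 4.5),
                        missing_rate = 0.02,
                        noise_sd = 0.05,
                        seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    sessions_per_participant = if (is.null(sessions_per_participant)) NULL else as.integer(sessions_per_participant),
    sampling_rate = sampling_rate,
    trials_per_session = trials_per_session,
    rest_duration = rest_duration,
    baseline_pupil_range = baseline_pupil_range,
    dilation_amplitude = dilation_amplitude,
    constriction_amplitude = constriction_amplitude,
    constriction_duration = constriction_duration,
    plr_amplitude_dpt = plr_amplitude_dpt,
    saccade_window = saccade_window,
    gaze_step_sd = gaze_step_sd,
    inter_trial_interval = inter_trial_interval,
    missing_rate = missing_rate,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_tepr_config(cfg)
  structure(cfg, class = "tepr_config")
}

validate_tepr_config <- function(cfg) {
  stopifnot(is.numeric(cfg$sampling_rate), length(cfg$sampling_rate) == 1L)
  if (cfg$sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (!all(TASKS %in% names(cfg$trials_per_session))) {
    abort("`trials_per_session` must name all of DPT, MA, PVT, VWM.")
  }
  if (any(cfg$trials_per_session < 1)) abort("trial counts must be >= 1.")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.2) {
    abort("`missing_rate` must lie in [0, 0.2].")
  }
  if (cfg$baseline_pupil_range[1] >= cfg$baseline_pupil_range[2]) {
    abort("`baseline_pupil_range` must be an increasing interval.")
  }
  if (cfg$inter_trial_interval[1] <= 3) {
    abort("`inter_trial_interval` lower bound must exceed 3 s (window separation).")
  }
  if (cfg$n_participants < 1) abort("`n_participants` must be >= 1.")
  invisible(cfg)
}

#' @export
print.tepr_config <- function(x, ...) {
  cat("<tepr_config>\n")
  cat("  participants:", x$n_participants,
      "| rate:", x$sampling_rate, "Hz",
      "| seed:", x$seed, "\n")
  cat("  trials/session:", paste(names(x$trials_per_session),
                                 x$trials_per_session, sep = "=", collapse = " "), "\n")
  cat("  baseline:", paste(x$baseline_pupil_range, collapse = "-"), "mm",
      "| dilation:", x$dilation_amplitude, "mm",
      "| DPT PLR:", x$plr_amplitude_dpt, "mm\n")
  cat("  missing rate:", x$missing_rate, "| noise sd:", x$noise_sd, "mm\n")
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic 31-bit sub-seed derived from a parent seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}
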