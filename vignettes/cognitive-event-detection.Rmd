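---
title: "Detecting cognitive events from task-evoked pupillary responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cognitive events from task-evoked pupillary responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilevents)
```

## The problem

A cognitive event — the onset of a stimulus that demands mental processing —
leaves a stereotyped trace in the eyes: the pupil briefly constricts, then
dilates by a few tenths of a millimetre as the sympathetic nervous system
responds to the new load, while gaze saccades toward the new information.
`pupilevents` frames the detection of such events as binary classification of
short windows of eye-tracking data (pupil diameter, gaze X, gaze Y, sampled
at 250 Hz): given one second of signal, did a stimulus onset just occur?

The package covers the full experimental loop: a synthetic-data generator
that emulates multi-session recordings across four classic cognitive tasks
(Dot Probe, Mental Arithmetic, Psychomotor Vigilance, Visual Working Memory)
plus rest; a sampling stage that turns recordings into standardized labeled
windows; four neural network architectures trained with a composite loss;
an evaluation suite built around the Matthews correlation coefficient (MCC);
permutation feature importance; and a causal online simulation with
rolling-baseline normalization.

## The synthetic generator

Real recordings of this kind are rarely public, so the generator is
first-class, tested code: every downstream stage is exercised on cohorts
whose ground truth is known exactly.

### Pupil model

Each recording is baseline + stimulus-locked responses + slow drift + white
noise. The stimulus-locked kernel is a sum of two smooth lobes:

* a **constriction** lobe, gamma-shaped with unit peak at
  `constriction_duration` (0.6 s): `(t / p)^k exp(k - t k / p)` with
  `k = 18`, deep enough that the combined kernel reaches its minimum at
  0.57–0.60 s;
* a **dilation** lobe, a delayed smooth ramp
  `s^2 / (s^2 + 0.3^2)`, `s = max(t - 0.3, 0)`, multiplied by a slow
  return-to-baseline envelope `plogis((2 - t) / 0.35)`, scaled by
  `dilation_amplitude` (0.2 mm by default — "a few tenths of a
  millimetre"). The envelope matters: task-evoked responses are transient,
  and without it the sustained plateau reads as a second event to a
  sliding-window detector.

Task identity enters only through the constriction amplitude: MA and VWM
carry the base depth (0.25 mm), PVT 30% of it (its displays change little in
luminance), and DPT adds `plr_amplitude_dpt` (0.8 mm) for the pupillary
light reflex its bright probes elicit, followed by re-dilation. The kernel is
exactly zero before the onset — no anticipatory response — and the functional
form is a package design choice: the morphology (trough at 0.6–0.7 s,
dilation above baseline by ~1 s, task ordering of trough depths) is the
constraint, the algebra is not.

### Gaze model

Gaze is fixation centre (500, 500 on the 0–1000 screen grid, origin
top-left) plus AR(1) fixation jitter plus per-trial trajectories: MA and PVT
trials make one saccade-like logistic step of magnitude ~`gaze_step_sd`
(77 x, 60 y screen units) completing inside `saccade_window` ([0, 0.5] s);
DPT trials stay put; VWM trials draw one of four programs (single saccade to
a random target, two-step scan, smooth sweep, hold) reflecting the varied
layouts of its memory arrays. Deviations fade back to fixation within ~3 s.

### Sessions, drift, missingness

Onsets are spaced by uniform inter-trial intervals whose lower bound (3.2 s)
exceeds 3 s so the pre-onset window of one trial can never touch the
post-onset window of its neighbour. Session baselines are drawn per
participant from `baseline_pupil_range` (3.5–4.5 mm) and perturbed per
session; a spline-smoothed random drift of at most 0.2 mm creates the slow
within-session variation that standardization must remove. Tracking dropouts
are contiguous `NA` runs of mean length 0.2 s placed in non-overlapping
strata at rate `missing_rate`; real dropout statistics are
unknowable here, so a run-length model is the documented stand-in. Everything is a
deterministic function of the config seed.

### What the generator does not emulate

No luminance physics, no blink kinematics, no coloured eye-tracker noise, no
demographic structure, and no fitted correspondence to any real dataset.
Passing tests therefore demonstrate that the *pipeline machinery* is correct
and that the method recovers events whose signature matches its assumptions;
they are not evidence about detection rates on real recordings.

## Sampling

Each session is standardized independently — per-feature z-scoring with the
session's own non-missing mean and sd — because equipment calibration,
lighting and participant state shift both baseline and scale between days.
For each onset at time T two windows are cut (half-open, the sample at the
interval start included): `[T - d, T)` labeled 0 and `[T + 0.5, T + 0.5 + d)`
labeled 1, with `d` the window duration (1 s by default; 0.5/2/3 s in the
duration ablation, which moves only the duration, never the 0.5-s offset).
The 0.5-s offset skips the constriction phase and the saccade so the
positive window captures the cognitive dilation itself. REST recordings
contribute random non-overlapping negatives; placement is slotted (the
recording is divided into window-length slots and a random subset taken),
which makes the non-overlap guarantee and the capacity bound exact. The
default number of REST windows per session is half the session's onset
count, yielding a 40% event-present prevalence; the original prevalences
imply an unstated REST window budget, so this is exposed as configuration.

Windows containing any missing value are dropped. SMOTE then equalizes the
training classes only: each synthetic window is a uniform convex combination
of a minority window and one of its five nearest minority neighbours
(Euclidean distance on the flattened time-by-feature vector; k = 5 is the
algorithm's canonical default, applied pooled across tasks rather than per
task). Validation and test sets keep their natural imbalance. Folds are
drawn at the participant level — sizes differing by at most one, 12/12/11/11/11
for 57 participants — and the split assembler verifies that no participant
appears in two of train/validation/test.

## Models

All four architectures share one skeleton: four stacked
architecture-specific layers, temporal average pooling (the last hidden
state for the RNN; skipped for the MLP), and a single affine head emitting
`1 + window_length` values — a classification logit and a pupil-diameter
reconstruction.

* **CNN**: per layer, valid 1-D convolution (64 channels, kernel 5,
  stride 1, no padding), ReLU, max pooling of size 2, dropout. Temporal
  sizes 250 → 123 → 59 → 27 → 11 are asserted against closed-form
  arithmetic in the tests.
* **BiLSTM**: forward and backward LSTMs of hidden size 64, concatenated to
  128 features per time step, dropout.
* **RNN**: the recurrence `h_t = M (W_x x_t + W_h h_{t-1} + b)`, hidden
  size 128, `h_0 = 0`, output `h_250`. As specified the recurrence has **no
  nonlinearity**; it is implemented exactly that way (a linear recurrence),
  flagged here and switchable to `tanh` via `rnn_nonlinearity`. Stability
  is kept by initializing the recurrent matrix with spectral radius ~0.5.
* **MLP**: the window is flattened (250 x 3 = 750), then four
  affine-ReLU-dropout layers of width 128.

Dropout (rate 0.3) uses the inverted convention so evaluation is exactly
deterministic. The loss is composite:
`L = CE(sigmoid(logit), y) + alpha * MAE(ReLU(recon), x_pupil)` with
`alpha = 0.004`; the reconstruction head exists for error checking — if a
stack cannot reproduce its own input channel, something is wrong upstream —
and the small `alpha` keeps it from competing with classification. The
cross-entropy clamps probabilities to `[1e-7, 1 - 1e-7]` before the log.

Forward and backward passes are written in base R matrix algebra (BLAS-backed
im2col convolutions, batched recurrences); no deep-learning framework is
involved. Analytic gradients for all four architectures are verified against
central finite differences to 1e-4 relative error in the test suite.

### Training

The original training protocol is unspecified beyond the loss, so the
package uses standard desk-scale choices, documented as its own: Adam at
learning rate 1e-3, batch size 64, up to 100 epochs, early stopping with
patience 10 on validation MCC, and best-validation-epoch weight selection.
With no validation set (toy runs) training MCC drives selection. All
randomness — initialization, batch order, dropout — derives from the config
seed, so repeated runs produce identical weight fingerprints. Classification
thresholds at 0.5 with ties going to class 0.

## Evaluation

MCC is the primary metric (robust to the imbalance the test sets keep);
accuracy, F1, sensitivity and specificity are reported alongside. Numerical
conventions, chosen where the definitions are silent: any zero factor in the
MCC denominator gives 0; empty denominators in the secondary metrics give 0.
Cross-model comparison uses the Pearson correlation of the binarized
predictions (the phi coefficient; a config flag allows probabilities, since
which of the two the original comparison used is unknowable from the text)
and the McNemar test on the discordance table of per-sample correctness:
exact binomial below 25 discordant pairs, continuity-corrected chi-square
above. Self-comparison yields 1.0 for both by construction.

## Permutation feature importance

Feature j's importance is the mean MCC drop over N = 100 random permutations
of that feature across the test windows, `I_j = mean(s_base - s_ij)`, with a
one-sample t-test of the drops against zero. "Shuffling all data within a
feature" is ambiguous between shuffling samples within each window and
swapping whole feature columns across windows; the package defaults to
**across-window block permutation** because it preserves within-window
temporal structure and therefore isolates the feature's informational
contribution rather than its autocorrelation, with `within_window = TRUE`
available as the alternative reading.

## Online simulation

Streaming replay is strictly causal: the first 60 s feed a per-feature
running mean/sd (Welford's single-pass update, missing samples skipped;
cumulative rather than sliding, because the baseline should keep absorbing
information as it arrives — a sliding variant would be a one-line change to
the state update). From `60 s + window` on, the trailing window is normalized
by the baseline available at that instant and scored every 0.1 s. Windows
touching missing samples yield flagged `NA` probabilities.

Scoring mirrors the offline labeling geometry, with three deliberate rules
where the original computation is unstated:

1. a detection is an upward 0.5-crossing that **holds** above threshold for
   at least 0.2 s (single-stride blips are transients, not events), computed
   on the live subsequence so a stream resuming above threshold after a
   dropout gap is not a fresh crossing; consecutive crossings within 0.5 s
   collapse into one;
2. an onset is a true positive when a detection falls in
   `[onset + 0.5, onset + 0.5 + duration + 0.5]` — the trailing 0.5-s
   latency allowance exists because a causal detector can only cross once
   its window has seen enough of the response; the pre-onset interval
   `[onset - duration, onset)` is the matched negative; leftover detections
   are false positives, after attributing detections to *all* onsets
   (including unscorable ones near the warm-up boundary);
3. scoring intervals overlapping missing predictions are excluded — the
   offline pipeline removes missing-sample windows rather than classifying
   them, and the online score should measure the model, not the dropout
   pattern.

On the package's strong-signal synthetic cohort this yields online MCC
within ~0.05 of the offline value, the same order of degradation the
offline-to-online transition is expected to cost.

## Problem sizes

The test suite and the acceptance script run at desk scale as a deliberate
choice: cohorts of 10 participants with one session each and 40/20/24/16
trials per task (the full-protocol 160/40/77/48 remain the config defaults),
CNN training capped at 6–8 epochs (the strong synthetic signal converges in
2–3), importance on up to 200 test windows, and streaming on the held-out
participants' recordings. At these sizes the full suite runs in a few
minutes on one CPU while exercising every stage at full fidelity.

## Known limitations

The RNN is linear as specified, which bounds what it can express; the
generator's missingness and drift models are conventions, not estimates; the
online scoring rule is a documented package choice, not a reconstruction of
the original; and synthetic separability is far better than real pupillometry,
so absolute MCC values here say nothing about field performance.
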