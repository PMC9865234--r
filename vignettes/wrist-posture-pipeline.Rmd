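---
title: "Estimating binned wrist posture from two inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating binned wrist posture from two inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ergonomic assessment tools (Strain Index, RULA, REBA) do not consume
continuous wrist angles; they consume *posture bins* — coarse angular
intervals judged frame by frame, traditionally by a human watching video.
`wristposture` implements an automated alternative: a convolutional window
classifier that maps one second of raw signal from two 6-DOF inertial
measurement units (IMUs), one on the dorsum of the hand and one on the
distal forearm, directly to the posture bin of the wrist, with no
sensor-to-segment calibration beyond approximate visual placement.

Two targets are classified independently:

* **Flexion/extension (FE)**, five bins:
  $\theta > 45^\circ$, $45^\circ \ge \theta > 15^\circ$,
  $15^\circ \ge \theta > -15^\circ$, $-15^\circ \ge \theta > -45^\circ$,
  $-45^\circ \ge \theta$ (upper edge inclusive, lower edge exclusive);
* **Radial/ulnar deviation (RU)**, three bins:
  $\theta \ge 10^\circ$, $10^\circ > \theta > -10^\circ$,
  $-10^\circ \ge \theta$.

The printed RU inequalities overlap at exactly $+10^\circ$; a deterministic
rule is mandatory, and this package assigns $+10^\circ$ to the radial (top)
bin, because the radial inequality is the closed one as listed. Both
binnings are exhaustive and mutually exclusive over the real line — a
property the test suite checks on a million sampled angles including every
boundary. Pronation/supination is simulated and recorded but never
classified.

Sign conventions are not dictated by the bin arithmetic, so they must be
pinned: this package takes **flexion positive** and **radial deviation
positive**, and `sim_config(fe_sign =, ru_sign =)` exposes flips should a
user's convention differ.

## The synthetic cohort

Real paired IMU/motion-capture recordings of this kind are generally
restricted by ethics boards, so the package ships a forward-kinematic
generator that emulates the *study design* and the *statistical character*
of such a dataset rather than any individual's data:

* **Design**: `n_participants` × 2 sessions × 2 repetitions × 3 tasks
  (`assembly`, `checkout`, `typing`), i.e. 12 recordings per participant and
  120 for the default 10-participant cohort, sampled at 100 Hz.
* **Durations**: 150 s (assembly), 130 s (checkout), 180 s (typing) —
  typing tasks in bench studies are conventionally three timed minutes, and
  the other durations are chosen so one participant contributes roughly
  half an hour (≈18,300 windows) across their 12 recordings.
* **Angles**: each task has a dwell profile — a mean posture and dispersion
  per channel, realized as band-limited Gaussian motion (< 5 Hz, most mass
  well below 2 Hz) — plus rare scripted high-flexion excursions
  (Poisson-timed raised-Gaussian bumps peaking between 55° and 85°). Every
  recording opens and closes with a scripted range-of-motion sweep in FE,
  RU and PS, as participants in such protocols are asked to perform.
  Dispersion values were calibrated once so that the pooled FE window
  labels of a default cohort place approximately 90% of their mass in the
  two dominant central bins ($15^\circ \ge \theta > -15^\circ$ and
  $-15^\circ \ge \theta > -45^\circ$) — the strong neutral-posture
  concentration characteristic of natural bench work — with the
  high-flexion bin rare (well under 1%).
* **Sensors**: the forearm follows a slow small random walk in orientation
  and position (standing bench posture; `forearm_walk_deg`,
  `forearm_drift_m`), and the hand is the forearm frame composed with
  rotations by PS, FE, RU about the anatomical axes. Gyroscope channels are
  the segment angular velocity expressed in the sensor frame, recovered
  from the orientation track via $[\omega]_\times = R^\top \dot R$
  (numerical differentiation, so the kinematic-consistency invariant holds
  by construction and is checked against analytic single-axis oracles in
  the tests). Accelerometer channels are specific force: gravity plus the
  linear acceleration of the sensor point on a simple articulated chain —
  included so that the accelerometers are moving-sensor signals rather than
  pure inclinometers. White noise (defaults 0.5 °/s and 0.05 m/s², typical
  of consumer MEMS parts after low-pass filtering) is added per channel.
* **Mounting error**: a fixed rotation per sensor, drawn once per
  participant with 5° SD per Euler axis and held across all of that
  participant's recordings — emulating "approximate visual alignment" and
  giving subject-specific refinement something real to adapt to.

What the generator does **not** emulate: soft-tissue artifact, magnetometer
channels (the modeled sensors are 6-DOF), sensor bias drift, task-specific
contact events (impacts when placing objects), or anthropometric variation
beyond mount misalignment. Passing tests on this cohort therefore
demonstrate that the pipeline is implemented correctly and can recover
posture under its stated assumptions — not that any particular accuracy
will transfer to human data.

The cohort is a pure function of `(n_participants, sim_config)`: every
stochastic stage derives its seed from the master seed by hash-chaining
(`derive_seed()`), so recordings are reproducible individually and
bit-identical across runs.

## Preprocessing

The order is fixed: **filter → normalize → window**.

* Angles are low-passed at 5 Hz and inertial channels at 6 Hz with a
  zero-lag (forward-backward) Butterworth filter. The order is 4 before the
  bidirectional pass — the convention in movement-kinematics work. The
  implementation uses odd-reflection padding and steady-state initial
  conditions, so a constant signal passes exactly and edge transients are
  suppressed; the tests assert DC fidelity, zero phase in the passband and
  >95% amplitude attenuation at four times the cutoff.
* Inertial channels are min–max normalized to [0, 1] **per channel, with
  parameters fitted on the training partition only**; held-out data is
  clipped into the training range. Fitting on all data would leak test
  information through the scaling. A degenerate channel (max = min) maps to
  0 with a warning.
* Recordings are restructured into 12 × 100 windows (1 s) with 90-sample
  overlap — 10 windows per second; a window's posture label is the mean of
  the 10 central samples of the filtered angle channels. For an even,
  100-sample window "the center" must be pinned: this package uses 0-based
  samples 45..54, the symmetric choice. Windows never span recording
  boundaries, and whether the range-of-motion sweeps enter the windowed set
  is a preprocessing switch (`include_rom_sweeps`, default `TRUE`).

## Class balancing

Natural bench work concentrates ~90% of windows in two of the five FE bins,
and a network trained on the raw stream mostly learns that prior. Balancing
is per recording: round each window's target angle to the nearest degree
(half away from zero — a pinned rule, since round-half-even would split the
two sides of 0° inconsistently), draw one representative window per
occupied 1° bin, then draw with replacement **from those representatives**
until exactly 250 examples exist. Drawing step 3 from all windows instead
of the representatives would restore the raw imbalance, which is why the
representative-only rule is the default (the alternative is deliberately
not offered). If more bins are occupied than examples requested — possible
only for pathologically wide motion — the representative set is uniformly
subsampled first. Each participant thus contributes 12 × 250 = 3000
training examples spread approximately evenly across their range of
motion. Separate balanced sets are drawn for the FE and RU models: the
channel being predicted is the channel balanced, since flattening one
cannot flatten the other.

## The classifier

A small CNN over the 12 × 100 × 1 block, valid (unpadded) convolutions
throughout: conv 3×3/32 → pool 2×2 → conv 3×3/64 → pool 2×2 → flatten
(1 × 23 × 64 = 1472) → dense 4096, ReLU, dropout 0.80 → softmax over 5 (FE)
or 3 (RU) classes. Valid padding is the choice that produces a coherent
shape chain from input to the 1472-long flatten; the test suite re-derives
the chain arithmetically. The implementation (RcppArmadillo) uses
im2col + GEMM with whole-mini-batch column concatenation, single precision,
and is verified against finite-difference gradients.

Training is two-phase:

1. **Initial**: mini-batch Adam (base learning rate 10⁻³, batch 64 — both
   unstated degrees of freedom pinned in `train_config()` and recorded in
   logs), categorical cross-entropy, a 10% validation split taken as the
   tail of the seeded shuffle, early stopping after 10 epochs without
   validation-loss improvement, hard limit 500 epochs. The reported weights
   are those of the **best validation epoch**, not the last.
2. **Refinement**: continued training on balanced windows from *session 1
   of the held-out participant only*, at one tenth of the base learning
   rate with patience 1 and a 50-epoch hard limit — aggressive early
   stopping to avoid overfitting the small subject-specific set. Guards
   reject refinement data from any other participant, from session 2, or
   from a participant present in initial training.

## Evaluation

Leave-one-subject-out: for each participant, train on everyone else's
balanced windows, refine on the held-out participant's session-1 balanced
windows, and test on **all raw (un-resampled) windows of their session-2
recordings** — session 1 was consumed by refinement, so unbiased testing
must exclude it. A hash audit over window identities (recording plus start
offset) proves no test window entered training or refinement.

Reported per target: per-fold and mean accuracy and Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$, with the across-fold standard error
$s/\sqrt{n_{\text{folds}}}$; the Landis–Koch qualitative label of the mean
$\kappa$; the cumulative contingency table (per-fold counts summed *before*
row normalization, so folds with more test windows weigh more, as a
cumulative table should); and per-class within-1-bin rates. Empty true-class
rows are reported as NaN and excluded from within-k averaging with a
warning rather than divided.

$\kappa$ is the right headline statistic here because test marginals are
heavily imbalanced: a classifier that always answered the two dominant bins
would score ~90% accuracy but $\kappa \approx 0$. The label-shuffled
control in the acceptance tests confirms the chance floor empirically.

## Numerical choices and problem sizes

* Single-precision arithmetic inside the trainer; weights round-trip
  through float, so exact-equality comparisons across a train call use a
  1e-6 tolerance. Argmax ties in prediction break toward the lower class
  index.
* All randomness flows from explicit integer seeds below 2³¹; cohort
  generation, resampling and training are deterministic given their seeds
  on fixed hardware in single-threaded BLAS mode (parallel BLAS may
  reorder floating-point reductions).
* The test suite exercises the full LOSO + refinement pipeline at desk
  scale: 3 participants, 60 s per task, low sensor noise, aligned mounts,
  and a reduced epoch budget (12 initial + 3 refinement). Under those
  conditions the pipeline reaches mean FE $\kappa \approx 0.75$ — the
  acceptance threshold is the Moderate boundary, $\kappa > 0.4$ — while the
  label-shuffled control sits within ±0.05 of zero. Full-scale runs
  (10 participants, default durations, full epoch budgets) use the same
  code path via `cmd_run_all()`.
* Generator calibration is checked on the full-scale default cohort:
  ~183,000 windows, of which 85–95% must fall in the two dominant FE bins.

## Limitations

The synthetic cohort is a model of a study, not a study. Absolute accuracy
and $\kappa$ on it say nothing quantitative about human data; the pipeline
properties that do transfer are the structural ones under test — leakage-free
fold construction, balanced training draws, deterministic preprocessing,
and a classifier capable of recovering posture from sensor physics when the
signal supports it. The refinement step personalizes the model to the test
subject; deployments without a ground-truth source for the first session
cannot use it, and generalization claims should then rest on the
unrefined model.
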