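---
title: "Multi-IMU error-state Kalman filtering for a 3-body walker: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-IMU error-state Kalman filtering for a 3-body walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Body-worn inertial measurement units (IMUs) deliver specific force and
angular rate at a few hundred hertz. Integrating them gives segment poses,
but integration drift makes the raw estimates useless within seconds.
`erkfgait` estimates the poses of the three segments of a simplified
lower-limb mechanism — a pelvis and two legs joined to it by hinge (pure
flexion/extension) joints, with one IMU welded to the sacrum and one to
each distal leg end — by fusing strapdown integration with four kinematic
pseudo-measurements inside one error-state Kalman filter (ESKF/ErKF):

* **Zero-velocity updates (ZUPT).** A foot is momentarily still after each
  ground contact; its velocity is then observed to be zero.
* **Gravitational tilt.** A still accelerometer reads pure gravity, so its
  unit direction observes world "up" in the body frame.
* **Joint-center coincidence.** The hip position computed from the pelvis
  chain and from the leg chain must agree:
  `h = p1 + R1 r1 - (p2 + R2 r2)`, observed as zero.
* **Joint-axis alignment.** The hinge axis expressed in the world frame
  through either adjacent segment must agree: `h = R1 e1 - R2 e2`,
  observed as zero.

Each IMU carries a 10-dimensional nominal state (position, velocity, unit
quaternion, Hamilton convention, body-to-world) and a 9-dimensional error
state (position, velocity, small attitude error `dtheta` with
`dq ~ [1, dtheta/2]`). The nominal state integrates the nonlinear strapdown
model; the filter propagates only the error covariance `P` (9n x 9n for n
IMUs, all cross-correlations retained) through the block-diagonal
first-order transition matrix. Measurements are stacked into a single batch
update per sample; the estimated error mean is injected into the nominal
states (`q <- q (x) dq`), reset to zero, and the covariance is mapped
through the reset Jacobian `G` whose attitude block is
`I - [dtheta_hat/2]x`. Biases and gravity are treated as known constants
and kept out of the state; a hook in `run_filter()` subtracts pre-estimated
constant gyro biases from incoming samples.

Sensor-to-segment alignment (joint-center offsets `r_i` and hinge axes
`e_i` in each IMU frame) is assumed known and constant, which on this
mechanism it is exactly.

## What the simulator emulates

`simulate_walker()` replaces the original motion-capture/physics pipeline
with a closed-form kinematic gait:

* 200 identical strides by default, stride length 0.73 m, mean speed
  0.33 m/s, 512 Hz sampling, and a 0.1 s full-body still period after every
  ground contact — the reference walking protocol.
* A move-pause compass cycle: during each step the stance leg pivots about
  its stationary foot from `+alpha` to `-alpha` while the swing leg mirrors
  it, both following a quintic smoothstep, so all pose series are C2 and
  every derivative the IMU model needs exists in closed form.
  `sin(alpha) = stride_length / (4 leg_length)` fixes the amplitude
  (`alpha ~ 11.4` degrees, flexion range of motion `2 alpha ~ 22.9`
  degrees). The pelvis keeps a constant orientation (the hips are pure
  hinges, so no pelvic list or rotation arises) and its height vaults over
  the stance leg. The published study states only that its waveform
  resembled the simplest walking model, so the point values of our angle
  and range-of-motion tables are approximate by construction; the error
  statistics, which are what the protocol evaluates, do not depend on the
  exact waveform shape.
* World frame: X forward, Y left, Z up; gravity `(0, 0, -9.81)` m/s^2.
  Body frames follow the biomechanical convention (x anterior, y superior,
  z right along the hinge axis).
* **Sensor model.** Samples are per-interval increments — the delta-v /
  delta-angle outputs of integrating strapdown IMUs: sample k reports the
  mean specific force (resolved at the sample-instant orientation) and the
  mean angular rate over `[t_k, t_k + dt]`. With this convention, open-loop
  re-integration of the ideal signals reproduces the true poses to about a
  micrometer over ten strides, so closed-loop errors are attributable to
  sensor noise rather than to a discretization mismatch between generator
  and filter. `synthesize_imu(convention = "instant")` provides plain
  instantaneous sampling instead.
* **Noise.** I.i.d. zero-mean Gaussian noise per axis and sample:
  accelerometers 0.027 m/s^2, gyroscopes 5.66 deg/s, plus a constant
  per-IMU gyro bias of 10 deg/hr in a seeded random direction. The slow
  drift component is modeled as a constant bias rather than a random walk:
  it is the simplest process with a secular effect of the quoted magnitude,
  and nothing in the protocol constrains its spectrum. All randomness is
  governed by one integer seed; runs are bit-reproducible.

What the simulator deliberately does **not** model: soft-tissue artefact,
sensor-to-segment misalignment, time-varying joint axes, non-hinge joint
play, turning gait, uneven terrain, accelerometer bias, or temperature
drift. Passing tests on this data therefore demonstrate the correctness
and noise response of the estimator on a rigid, perfectly calibrated
mechanism — the same isolation argument the walker protocol itself makes —
not performance on human gait.

## Noise parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `sigma_a` | 0.027 | m/s^2 | accelerometer noise; process noise `sigma_a^2 dt^2` on velocity |
| `sigma_w` | 5.66 | deg/s | gyroscope noise; process noise `sigma_w^2 dt^2` on attitude |
| `sigma_zv` | 0.01 | m/s | ZUPT measurement SD |
| `sigma_tilt` | 5.73 | deg | tilt measurement SD (unit-vector residual) |
| `sigma_jc` | 0.01 | m | joint-center measurement SD |
| `sigma_ja` | 1.15 | deg | joint-axis measurement SD |

**The joint-axis noise unit.** The study's noise table nominally lists the
joint-axis entry as 1.15 *radians* (66 degrees). A constraint that weak
leaves relative yaw essentially unobserved between joint-center updates:
with it, the filter's internal/external rotation RMS lands around
0.4–0.7 degrees, which no tuning reconciles with the reported
0.09-degree accuracy. Read as 1.15 *degrees* (0.0201 rad — exactly the
kind of deg/rad slip suggested by the neighboring tilt entry, 5.73 deg =
0.100 rad), the filter reproduces all three reported angle RMS values at
their printed precision. We therefore default to degrees and expose
`noise_params(sigma_ja = 1.15)` for the literal radian reading.

Other numerical and scheduling choices made where the protocol is silent:

* Initial covariance: diagonal, 1e-3 m, 1e-3 m/s, 1 degree per axis — a
  trial starts from a known still pose.
* Initial state: roll/pitch of each IMU from its mean accelerometer
  direction over the first still window (shortest-arc alignment, yaw zero
  for every IMU — global heading is unobservable and only relative yaw,
  which the joint corrections recover, matters for joint angles);
  positions chained through the joint centers from the pelvis; velocities
  zero.
* ZUPT and tilt are applied at every sample inside a still window (the
  conservative reading of "applied at footfalls/still periods"); ZUPT
  targets the foot that owns the window, tilt targets all three IMUs
  because the walker pauses entirely. Both are configurable
  (`measurement_schedule()`), including collapsing ZUPT to the single
  footfall instant.
* Joint-center and joint-axis corrections run at every sample: the hips
  are permanent hinges on this mechanism.
* The innovation covariance is solved by Cholesky factorization (never
  inverted explicitly; a diagonal-ratio condition guard aborts at 1e12);
  the covariance is re-symmetrized after every predict and update, which
  over ~2e5 steps keeps the smallest eigenvalue at the +1e-8 level.
* Measurement batches use a fixed canonical order (ZUPT, tilt,
  joint-center, joint-axis; left before right); the posterior is
  order-independent and the suite verifies this.
* The quaternion exponential switches to its series form below 1e-8 rad;
  quaternion signs are only canonicalized at I/O boundaries.

## Gait analysis conventions

Hip angles decompose the relative pelvis-to-leg rotation by the mobile
Z-X-Y sequence of the ISB hip convention: flexion about the pelvis z
(hinge) axis, ab/adduction about the floating x axis, internal/external
rotation about the leg y axis; left-side ab/adduction and internal
rotation are sign-mirrored so positive is medially directed on both sides.
On this mechanism the true non-sagittal angles are identically zero, which
the suite asserts to 1e-9 degrees.

Footfalls are the midpoints of the still windows. Stride length is the
horizontal displacement of a foot IMU between consecutive same-foot
footfalls. Step width is the separation of the two feet's footfall
positions perpendicular to a *time-local* travel direction — the leading
foot's own stride displacement. A trial-wide principal direction (from the
sacrum displacement) is used for the straight-stride filter (within 15
degrees of the principal direction and longer than 0.2 m) and as the
fallback travel frame; the local frame matters because global heading is
unobservable to the filter, so a slow heading wander would otherwise leak
the forward step component into the lateral separation. Each leg's first
(transition) stride is excluded from every comparison, as in the reference
evaluation. Comparison statistics are per-sample mean, SD and RMS of
estimate-minus-truth, per-stride range-of-motion differences for
flexion/extension, least-squares drift slopes in deg/hr, and Bland-Altman
95% limits of agreement (`mean +/- 1.96 SD`) for method-comparison use.

The still-period detector (`detect_still_periods()`) thresholds the
gyroscope magnitude (2 deg/s), the deviation of the accelerometer
magnitude from gravity (0.5 m/s^2) and a minimum duration (0.05 s). It is
intended for clean or lightly filtered signals; at the reference noise
level (gyro 5.66 deg/s per sample) raw-signal detection is not meaningful,
and the pipeline follows the reference protocol in using the annotated
event times directly. On noise-free data the detector recovers every
annotated window, with boundaries displaced by the ~55 ms it takes the C2
waveform to cross the rate threshold.

## Problem sizes used by the suite

The packaged tests exercise the full default protocol once (200 strides,
about 2.3e5 samples, roughly four minutes of filtering on one core) and
reuse that run across the accuracy checks (angle RMS, stride/step
percentages, drift slopes, covariance health); scaled 20-stride runs cover
the open-question configurations (no joint-axis correction, scaled
accuracy gate), 10 strides the noise-free consistency run, and 3-5 strides
the geometry and pipeline contracts. `scripts/acceptance.R` recomputes the
headline quantities from scratch at the full scale.

## Known limitations

* The waveform is one specific realization of the stated protocol;
  absolute range-of-motion and point kinematics differ from the original
  (unpublished) trajectories, so only noise-driven error statistics are
  comparable.
* Global position and heading are unobservable by design; all reported
  metrics are invariant to them, but raw trajectories are only defined up
  to that gauge.
* The filter assumes a constant, known sensor-to-segment alignment and
  known constant biases; neither is estimated online.
* No magnetometer fusion, no smoothing (RTS) pass, no adaptive noise
  tuning; the experimental (motion-capture) half of the original study is
  out of scope, and Bland-Altman tooling is provided only as a generic
  statistic.
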