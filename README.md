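# erkfgait

Multi-IMU error-state Kalman filtering for lower-limb gait kinematics,
evaluated on a 3-body "walker" mechanism (a pelvis and two legs joined by
hinge joints, with one IMU on the sacrum and one on each distal leg end).

Strapdown integration of body-worn IMU data drifts within seconds. This
package corrects that drift by fusing, in a single error-state Kalman
filter (ESKF) over all IMUs jointly, four kinematic pseudo-measurements:

* **ZUPT** — a momentarily still foot has zero velocity: `h(x) = v_imu`,
  `z = 0`;
* **gravitational tilt** — a still accelerometer observes world up in the
  body frame: `h(x) = R^T [0, 0, 1]`, `z = a / |a|`;
* **joint-center coincidence** — the hip position agrees through either
  adjacent segment: `h(x) = p_1 + R_1 r_1 - (p_2 + R_2 r_2)`, `z = 0`;
* **joint-axis alignment** — the hinge axis agrees through either segment:
  `h(x) = R_1 e_1 - R_2 e_2`, `z = 0`.

Each IMU's nominal state `x_j = (p_j, v_j, q_j)` integrates the nonlinear
strapdown model; the filter estimates the small error state
`(dp, dv, dtheta)` per IMU with one joint covariance, injects the
estimated error into the nominal states after each batch update, and
resets it to zero with the proper reset Jacobian. The package also ships a
closed-form synthetic walker-gait simulator (ground-truth poses, ideal and
noisy IMU signals, event annotations), gait analysis (ISB hip angles,
stride length, step width, drift slopes, Bland-Altman limits), and a
reproducible simulate–filter–analyze pipeline. It is aimed at researchers
developing inertial motion-capture estimators who need a controlled,
fully-characterized testbed.

## Worked example

A scaled 20-stride version of the default protocol (stride length 0.73 m,
mean speed 0.33 m/s, 0.1 s still periods, 512 Hz, reference sensor noise):

```r
library(erkfgait)

rec  <- simulate_walker(gait_params(n_strides = 20, seed = 7))
traj <- run_filter(rec$imu, rec$t, rec$rig, noise_params(),
                   measurement_schedule(rec$events))
analyze_trial(rec, traj)
#> Hip joint angle differences, pooled across hips (deg):
#>      angle     mean     sd    rms rom_mean rom_sd rom_rms
#>    flexion  0.00144 0.1650 0.1650    0.311  0.246   0.394
#>   internal -0.00436 0.0897 0.0898       NA     NA      NA
#>  abduction  0.00335 0.0828 0.0828       NA     NA      NA
#> Drift slopes (right hip, deg/hr): flexion -1.94, internal 0.566, abduction 0.964
#> Stride length: RMS diff 0.0021 m (0.28%), n = 37
#> Step width:    RMS diff 0.0012 m (0.31%), n = 38
```

Reading: per-sample hip-angle errors (estimate minus truth, pooled over
both hips, each leg's first stride excluded) stay below 0.2 deg RMS on all
three components; per-stride spatiotemporal errors are around two
millimetres (well under 1% of the 0.73 m stride length and of the 0.39 m
step width). Drift slopes shrink towards zero as the trial lengthens (they
are slope-of-noise on a 44 s run; the 200-stride run brings them to about
0.1 deg/hr, the noise floor of the fit). An open-loop run
(`measurement_schedule(rec$events, enable = character(0))`) shows the
uncorrected errors growing to degrees over the same span.

The same stages are scriptable from a shell via the thin CLI in
`inst/cli/erkfgait` (`simulate`, `filter`, `analyze`, `pipeline`), which
exchange CSV/YAML/JSON files and record a full manifest per run.

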