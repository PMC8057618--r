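# Synthetic 3-body walker: ground-truth kinematics, ideal and noisy IMU
# signals, and event annotations.
#
# World frame: X forward, Y left, Z up (gravity along -Z). Body frames (all
# segments, neutral upright pose): x anterior, y superior, z to the right --
# the hinge axis. The neutral body-to-world rotation is therefore a +90 deg
# rotation about world X.
#
# The gait is a move-pause compass cycle. At each ground contact the whole
# model freezes for the still duration; then the stance leg pivots about its
# stationary foot from +alpha to -alpha while the swing leg mirrors it
# (-alpha to +alpha), both through a C2 quintic smoothstep, so every pose
# series is twice continuously differentiable and all IMU signals follow in
# closed form. alpha is fixed by the stride length:
# sin(alpha) = stride_length / (4 leg_length).

# Neutral body-to-world quaternion: +90 deg about world X.
.q_neutral <- c(cos(pi / 4), sin(pi / 4), 0, 0)

#' Walker rig geometry
#'
#' Three IMUs: 1 = pelvis (sacrum), 2 = left foot, 3 = right foot, each
#' welded to its segment (identity mounts by default: IMU frame equals
#' segment frame, pelvis IMU at the pelvis center, foot IMUs at the distal
#' leg ends). The two hips are hinges about the shared body z-axis.
#'
#' @param leg_length Leg length, m.
#' @param pelvis_width Distance between the hip joints, m.
#' @param imu_mounts Optional list of per-IMU mounts, each
#'   `list(t = offset in segment frame (m), q = mount quaternion)`.
#' @return A list of class `walker_rig` with joint geometries.
#' @export
walker_rig <- function(leg_length = 0.92, pelvis_width = 0.39,
                       imu_mounts = NULL) {
  stopifnot(leg_length > 0, pelvis_width > 0)
  if (is.null(imu_mounts)) {
    imu_mounts <- rep(list(list(t = c(0, 0, 0), q = c(1, 0, 0, 0))), 3L)
  }
  w2 <- pelvis_width / 2
  joints <- list(
    left = joint_geometry(1L, 2L, r_a = c(0, 0, -w2),
                          r_b = c(0, leg_length, 0),
                          e_a = c(0, 0, 1), e_b = c(0, 0, 1)),
    right = joint_geometry(1L, 3L, r_a = c(0, 0, w2),
                           r_b = c(0, leg_length, 0),
                           e_a = c(0, 0, 1), e_b = c(0, 0, 1))
  )
  structure(list(leg_length = leg_length, pelvis_width = pelvis_width,
                 imu_names = c("pelvis", "left_foot", "right_foot"),
                 base_imu = 1L, imu_mounts = imu_mounts, joints = joints),
            class = "walker_rig")
}

#' Gait protocol parameters
#'
#' Defaults reproduce the reference walking protocol: 200 identical strides,
#' stride length 0.73 m, mean speed 0.33 m/s, 0.1 s still period after each
#' ground contact, 512 Hz sampling.
#'
#' @param n_strides Number of strides (right-foot cycles).
#' @param stride_length Stride length, m.
#' @param mean_speed Mean forward speed, m/s.
#' @param still_duration Still period after each ground contact, s.
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed for the sensor-noise generator.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(n_strides = 200L, stride_length = 0.73,
                        mean_speed = 0.33, still_duration = 0.1,
                        sample_rate = 512, seed = 1L) {
  stopifnot(n_strides >= 1L, stride_length > 0, mean_speed > 0,
            still_duration >= 0, sample_rate > 0)
  t_stride <- stride_length / mean_speed
  if (t_stride / 2 <= still_duration) {
    stop("gait_params: still_duration must be shorter than half a stride period")
  }
  structure(list(n_strides = as.integer(n_strides),
                 stride_length = stride_length, mean_speed = mean_speed,
                 still_duration = still_duration, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "gait_params")
}

# Quintic smoothstep and derivatives: C2 with zero slope/curvature at 0 and 1.
.smoothstep <- function(x) x^3 * (10 + x * (-15 + 6 * x))
.smoothstep_d1 <- function(x) 30 * x^2 * (1 - x)^2
.smoothstep_d2 <- function(x) 60 * x * (1 - 3 * x + 2 * x^2)

#' Generate the walker's joint-coordinate trajectories
#'
#' Produces hip flexion angles for both legs (antiphase) and the pelvis
#' trajectory for a straight-line walk with still windows after every ground
#' contact, together with first and second time derivatives (closed form)
#' and the event annotations.
#'
#' @param params A [gait_params()].
#' @param rig A [walker_rig()].
#' @param times Optional explicit evaluation times, s; defaults to the
#'   uniform sampling grid implied by `params`. The closed-form waveform can
#'   be evaluated at arbitrary instants (used e.g. to synthesize
#'   interval-midpoint sensor samples).
#' @return A list of class `gait_coords` with fields `t`, `theta_r`,
#'   `theta_l` (+ `_d1`, `_d2`; rad, rad/s, rad/s^2), `pelvis_p`, `pelvis_v`,
#'   `pelvis_a` (n x 3), and `events` (data.frame: foot, t_contact,
#'   t_still_start, t_still_end).
#' @export
generate_gait <- function(params = gait_params(), rig = walker_rig(),
                          times = NULL) {
  L <- rig$leg_length
  if (params$stride_length > 2 * L) {
    stop("generate_gait: stride_length ", params$stride_length,
         " m is infeasible for leg length ", L, " m")
  }
  sin_a <- params$stride_length / (4 * L)
  alpha <- asin(sin_a)
  t_step <- params$stride_length / params$mean_speed / 2
  d <- params$still_duration
  tau <- t_step - d
  step_len <- params$stride_length / 2
  n_steps <- 2L * params$n_strides
  duration <- n_steps * t_step + d
  fs <- params$sample_rate
  t <- if (is.null(times)) {
    seq(0, by = 1 / fs, length.out = floor(duration * fs) + 1L)
  } else {
    as.numeric(times)
  }

  k <- pmin(floor(t / t_step), n_steps - 1)
  u <- t - k * t_step
  x <- pmin(pmax((u - d) / tau, 0), 1)
  s <- .smoothstep(x)
  active <- u >= d & u <= t_step            # swing phase of the current step
  s1 <- ifelse(active, .smoothstep_d1(x) / tau, 0)
  s2 <- ifelse(active, .smoothstep_d2(x) / tau^2, 0)

  th_st <- alpha * (1 - 2 * s)              # stance-leg hip angle
  th_st1 <- -2 * alpha * s1
  th_st2 <- -2 * alpha * s2
  right_stance <- (k %% 2) == 0
  sgn <- ifelse(right_stance, 1, -1)
  theta_r <- sgn * th_st; theta_r_d1 <- sgn * th_st1; theta_r_d2 <- sgn * th_st2
  theta_l <- -theta_r;    theta_l_d1 <- -theta_r_d1; theta_l_d2 <- -theta_r_d2

  # pelvis center follows the stance-leg chain (stance foot is stationary)
  x_contact <- k * step_len
  ct <- cos(th_st); st <- sin(th_st)
  pelvis_p <- cbind(x_contact - L * st, 0, L * ct)
  pelvis_v <- cbind(-L * ct * th_st1, 0, -L * st * th_st1)
  pelvis_a <- cbind(-L * (ct * th_st2 - st * th_st1^2), 0,
                    -L * (st * th_st2 + ct * th_st1^2))

  contacts <- 0:n_steps
  events <- data.frame(
    foot = ifelse(contacts %% 2 == 0, "right", "left"),
    t_contact = contacts * t_step,
    t_still_start = contacts * t_step,
    t_still_end = pmin(contacts * t_step + d, max(t)),
    stringsAsFactors = FALSE
  )

  structure(list(t = t, dt = 1 / fs, alpha = alpha,
                 theta_r = theta_r, theta_r_d1 = theta_r_d1, theta_r_d2 = theta_r_d2,
                 theta_l = theta_l, theta_l_d1 = theta_l_d1, theta_l_d2 = theta_l_d2,
                 pelvis_p = pelvis_p, pelvis_v = pelvis_v, pelvis_a = pelvis_a,
                 events = events, params = params),
            class = "gait_coords")
}

# Rotate body-frame row vectors by per-row quaternions (body -> world).
.rotate_rows <- function(qm, vm) {
  w <- qm[, 1L]; ux <- qm[, 2L]; uy <- qm[, 3L]; uz <- qm[, 4L]
  vx <- vm[, 1L]; vy <- vm[, 2L]; vz <- vm[, 3L]
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  ccx <- uy * cz - uz * cy
  ccy <- uz * cx - ux * cz
  ccz <- ux * cy - uy * cx
  cbind(vx + 2 * (w * cx + ccx), vy + 2 * (w * cy + ccy), vz + 2 * (w * cz + ccz))
}

# Per-row quaternion product (n x 4 times n x 4 or length-4).
.qmult_rows <- function(q1, q2) {
  if (is.null(dim(q2))) q2 <- matrix(q2, nrow(q1), 4L, byrow = TRUE)
  if (is.null(dim(q1))) q1 <- matrix(q1, nrow(q2), 4L, byrow = TRUE)
  w1 <- q1[, 1L]; x1 <- q1[, 2L]; y1 <- q1[, 3L]; z1 <- q1[, 4L]
  w2 <- q2[, 1L]; x2 <- q2[, 2L]; y2 <- q2[, 3L]; z2 <- q2[, 4L]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Forward kinematics: IMU pose series from joint coordinates
#'
#' Computes the world pose (and analytic velocity, acceleration, body
#' angular rate) of each IMU. Segment poses follow the kinematic chain from
#' the pelvis through the hip hinges; IMU mounts are applied on top. Both
#' legs' chains pass through their shared joint center, so joint positions
#' computed from either adjacent segment agree to machine precision.
#'
#' @param coords A [gait_coords()] from [generate_gait()].
#' @param rig A [walker_rig()].
#' @return A list of class `imu_poses`: per IMU, `p`, `v`, `a` (n x 3, world),
#'   `q` (n x 4, body to world), `omega` (n x 3, body frame, rad/s).
#' @export
forward_kinematics <- function(coords, rig) {
  n <- length(coords$t)
  L <- rig$leg_length
  w2 <- rig$pelvis_width / 2
  q0 <- .q_neutral

  # pelvis segment: constant orientation, translating
  pel <- list(p = coords$pelvis_p, v = coords$pelvis_v, a = coords$pelvis_a,
              q = matrix(q0, n, 4L, byrow = TRUE),
              omega = matrix(0, n, 3L))

  leg <- function(theta, d1, d2, side_sign) {
    # hip position: pelvis center offset laterally (world Y: left +, right -)
    hip_off <- c(0, -side_sign * w2, 0)
    st <- sin(theta); ct <- cos(theta)
    p <- cbind(coords$pelvis_p[, 1L] + L * st,
               coords$pelvis_p[, 2L] + hip_off[2L],
               coords$pelvis_p[, 3L] - L * ct)
    v <- cbind(coords$pelvis_v[, 1L] + L * ct * d1,
               coords$pelvis_v[, 2L],
               coords$pelvis_v[, 3L] + L * st * d1)
    a <- cbind(coords$pelvis_a[, 1L] + L * (ct * d2 - st * d1^2),
               coords$pelvis_a[, 2L],
               coords$pelvis_a[, 3L] + L * (st * d2 + ct * d1^2))
    # q = q_neutral (x) q_z(theta)
    ch <- cos(theta / 2); sh <- sin(theta / 2)
    a0 <- q0[1L]; b0 <- q0[2L]
    q <- cbind(a0 * ch, b0 * ch, -b0 * sh, a0 * sh)
    list(p = p, v = v, a = a, q = q, omega = cbind(0, 0, d1))
  }

  segs <- list(pelvis = pel,
               left_foot = leg(coords$theta_l, coords$theta_l_d1,
                               coords$theta_l_d2, -1),
               right_foot = leg(coords$theta_r, coords$theta_r_d1,
                                coords$theta_r_d2, 1))

  # apply IMU mounts (offset t_m and rotation q_m in the segment frame)
  out <- vector("list", 3L)
  for (j in 1:3) {
    sg <- segs[[j]]
    m <- rig$imu_mounts[[j]]
    if (all(m$t == 0) && all(m$q == c(1, 0, 0, 0))) {
      out[[j]] <- sg
      next
    }
    tm <- matrix(m$t, n, 3L, byrow = TRUE)
    om <- sg$omega
    # world lever arm and its rates: r = R t, dr = R (w x t), etc.
    wxt <- cbind(om[, 2L] * tm[, 3L] - om[, 3L] * tm[, 2L],
                 om[, 3L] * tm[, 1L] - om[, 1L] * tm[, 3L],
                 om[, 1L] * tm[, 2L] - om[, 2L] * tm[, 1L])
    # omega dot: only z-rate varies for the legs; recover from finite diff-free
    # closed form: for these segments omega = (0,0,d1), omegadot = (0,0,d2)
    omd <- if (j == 1L) matrix(0, n, 3L) else
      cbind(0, 0, if (j == 2L) coords$theta_l_d2 else coords$theta_r_d2)
    wdxt <- cbind(omd[, 2L] * tm[, 3L] - omd[, 3L] * tm[, 2L],
                  omd[, 3L] * tm[, 1L] - omd[, 1L] * tm[, 3L],
                  omd[, 1L] * tm[, 2L] - omd[, 2L] * tm[, 1L])
    wxwxt <- cbind(om[, 2L] * wxt[, 3L] - om[, 3L] * wxt[, 2L],
                   om[, 3L] * wxt[, 1L] - om[, 1L] * wxt[, 3L],
                   om[, 1L] * wxt[, 2L] - om[, 2L] * wxt[, 1L])
    out[[j]] <- list(
      p = sg$p + .rotate_rows(sg$q, tm),
      v = sg$v + .rotate_rows(sg$q, wxt),
      a = sg$a + .rotate_rows(sg$q, wdxt + wxwxt),
      q = .qmult_rows(sg$q, m$q),
      omega = .rotate_rows(matrix(quat_conjugate(m$q), n, 4L, byrow = TRUE), om)
    )
  }
  names(out) <- rig$imu_names
  structure(c(out, list(t = coords$t)), class = "imu_poses")
}

#' Synthesize ideal IMU signals from pose series
#'
#' Inverts the strapdown model: the gyroscope reads the body-frame angular
#' rate and the accelerometer reads the specific force `R^T (p_ddot - g)`,
#' so a still, level IMU reads `(0, 0, 9.81)`. Uses the analytic velocity,
#' acceleration and angular-rate series when present; otherwise falls back
#' to central differences (one-sided at the end points).
#'
#' @param poses An `imu_poses` object evaluated at the sample timestamps.
#' @param dt Sampling period, s.
#' @param g World gravity vector, m/s^2.
#' @param convention `"increment"` (default) models integrating sensors:
#'   sample k reports the mean specific force and angular rate over
#'   `[t_k, t_k + dt]`, computed from the velocity and orientation increments
#'   (the delta-v / delta-angle outputs of real strapdown IMUs); the last
#'   sample uses the trailing backward increment. `"instant"` reports the
#'   instantaneous values at the sample times.
#' @return Per IMU: list with `a` (n x 3, m/s^2) and `w` (n x 3, rad/s).
#' @export
synthesize_imu <- function(poses, dt, g = c(0, 0, -9.81),
                           convention = c("increment", "instant")) {
  convention <- match.arg(convention)
  one <- function(sg) {
    n <- nrow(sg$p)
    gm <- matrix(g, n, 3L, byrow = TRUE)
    vv <- if (!is.null(sg$v)) sg$v else .diff_central(sg$p, dt)
    qc <- cbind(sg$q[, 1L], -sg$q[, 2L], -sg$q[, 3L], -sg$q[, 4L])
    if (convention == "instant") {
      acc <- if (!is.null(sg$a)) sg$a else .diff_central(vv, dt)
      om <- sg$omega
      if (is.null(om)) om <- .q_rate_rows(sg$q, dt)
      return(list(a = .rotate_rows(qc, acc - gm), w = om))
    }
    # increment convention: a_k = R_k^T ((v_{k+1} - v_k)/dt - g),
    # w_k = log(q_k^-1 (x) q_{k+1}) / dt; backward increment for the last row
    dv <- rbind(diff(vv), vv[n, ] - vv[n - 1L, ]) / dt
    dq <- .qmult_rows(qc, sg$q[c(2:n, n), , drop = FALSE])
    dq[n, ] <- quat_multiply(quat_conjugate(sg$q[n - 1L, ]), sg$q[n, ])
    om <- .rowlog(dq) / dt
    list(a = .rotate_rows(qc, dv - gm), w = om)
  }
  imu_names <- setdiff(names(poses), "t")
  out <- lapply(imu_names, function(nm) one(poses[[nm]]))
  names(out) <- imu_names
  structure(out, class = "imu_signals")
}

# Row-wise quaternion logarithm: rotation vectors of n x 4 unit quaternions.
.rowlog <- function(qm) {
  sgn <- ifelse(qm[, 1L] < 0, -1, 1)
  w <- qm[, 1L] * sgn
  v <- qm[, 2:4, drop = FALSE] * sgn
  s <- sqrt(rowSums(v^2))
  phi <- 2 * atan2(s, w)
  fac <- ifelse(s < 1e-12, 2, phi / pmax(s, 1e-300))
  v * fac
}

# Instantaneous body angular rate from a quaternion series, central diff.
.q_rate_rows <- function(qm, dt) {
  n <- nrow(qm)
  ip <- c(2:n, n); im <- c(1L, 1:(n - 1L))
  qc <- cbind(qm[im, 1L], -qm[im, 2L], -qm[im, 3L], -qm[im, 4L])
  dq <- .qmult_rows(qc, qm[ip, , drop = FALSE])
  .rowlog(dq) / ((ip - im) * dt)
}

.diff_central <- function(x, dt) {
  n <- nrow(x)
  d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) /
    (c(1, rep(2, n - 2), 1) * dt)
  d
}

#' Add sensor noise and gyro bias to ideal IMU signals
#'
#' Adds i.i.d. zero-mean Gaussian noise per axis and sample (accelerometer
#' `sigma_a`, gyroscope `sigma_w`) and, optionally, a constant per-IMU gyro
#' bias of the given magnitude in a seeded random direction, modeling the
#' slow drift component quoted for the sensors. Deterministic given `seed`;
#' the caller's RNG state is left untouched.
#'
#' @param signals An `imu_signals` object.
#' @param np A [noise_params()].
#' @param gyro_bias Gyro bias magnitude, rad/s (0 disables).
#' @param seed Integer seed.
#' @return An `imu_signals` object with noisy `a`, `w` (and the drawn bias
#'   per IMU in field `bias_w`).
#' @export
add_noise <- function(signals, np, gyro_bias = 10 / 3600 * pi / 180, seed = 1L) {
  .with_seed(seed, {
    out <- lapply(signals, function(sg) {
      n <- nrow(sg$a)
      b <- c(0, 0, 0)
      if (gyro_bias > 0) {
        dir <- stats::rnorm(3L)
        b <- gyro_bias * dir / sqrt(sum(dir^2))
      }
      list(a = sg$a + matrix(stats::rnorm(3L * n, sd = np$sigma_a), n, 3L),
           w = sg$w + matrix(stats::rnorm(3L * n, sd = np$sigma_w), n, 3L) +
             matrix(b, n, 3L, byrow = TRUE),
           bias_w = b)
    })
    structure(out, class = "imu_signals")
  })
}

# Evaluate expr with a temporary RNG state; restores the caller's state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a complete walker trial
#'
#' Chains [generate_gait()], [forward_kinematics()], [synthesize_imu()] and
#' [add_noise()] into a single ground-truth record.
#'
#' @param params A [gait_params()].
#' @param rig A [walker_rig()].
#' @param np A [noise_params()].
#' @param gyro_bias Constant gyro bias magnitude, rad/s.
#' @param noisy If `FALSE`, the returned `imu` signals are the ideal ones.
#' @return A list of class `gait_record`: `t`, `dt`, `truth` (IMU poses),
#'   `imu` (noisy signals), `imu_ideal`, `events`, `true_angles`
#'   (data.frame: t, right, left flexion in degrees), `rig`, `params`, `np`.
#' @export
simulate_walker <- function(params = gait_params(), rig = walker_rig(),
                            np = noise_params(),
                            gyro_bias = 10 / 3600 * pi / 180,
                            noisy = TRUE) {
  coords <- generate_gait(params, rig)
  truth <- forward_kinematics(coords, rig)
  ideal <- synthesize_imu(truth, coords$dt, np$g)
  imu <- if (noisy) add_noise(ideal, np, gyro_bias, params$seed) else ideal
  true_angles <- data.frame(t = coords$t,
                            right = coords$theta_r * 180 / pi,
                            left = coords$theta_l * 180 / pi)
  structure(list(t = coords$t, dt = coords$dt, coords = coords, truth = truth,
                 imu = imu, imu_ideal = ideal, events = coords$events,
                 true_angles = true_angles, rig = rig, params = params,
                 np = np),
            class = "gait_record")
}

#' @export
print.gait_record <- function(x, ...) {
  cat(sprintf(
    "<gait_record: %d strides, %.1f s at %g Hz (%d samples), %d events>\n",
    x$params$n_strides, max(x$t), x$params$sample_rate, length(x$t),
    nrow(x$events)))
  invisible(x)
}
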