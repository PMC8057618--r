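# Multi-IMU error-state Kalman filter core.
#
# Each IMU carries a 10-component nominal state (position p, velocity v, unit
# quaternion q, all world-frame except q which maps body to world) and a
# 9-component error state (dp, dv, dtheta). The system state concatenates n
# IMUs; the single covariance P (9n x 9n) carries all cross-IMU correlations,
# which is what lets a correction on one IMU inform the others.

#' Nominal state of a single IMU
#'
#' @param p Numeric length-3 world-frame position of the accelerometer, m.
#' @param v Numeric length-3 world-frame velocity, m/s.
#' @param q Numeric length-4 unit quaternion (body to world, scalar first).
#' @return An object of class `imu_state`.
#' @export
imu_state <- function(p = c(0, 0, 0), v = c(0, 0, 0), q = c(1, 0, 0, 0)) {
  stopifnot(length(p) == 3L, length(v) == 3L, length(q) == 4L,
            all(is.finite(p)), all(is.finite(v)), all(is.finite(q)))
  structure(list(p = as.numeric(p), v = as.numeric(v),
                 q = quat_normalize(as.numeric(q))),
            class = "imu_state")
}

#' Full system state: n IMU states plus joint error covariance
#'
#' @param imus List of [imu_state()] objects.
#' @param P Error-state covariance, `9n x 9n`, SI units. Defaults to the
#'   standard still-start prior: 1e-3 m, 1e-3 m/s and 1 degree (per axis)
#'   standard deviations.
#' @return An object of class `system_state`.
#' @export
system_state <- function(imus, P = NULL) {
  n <- length(imus)
  if (is.null(P)) {
    sd9 <- c(rep(1e-3, 3L), rep(1e-3, 3L), rep(pi / 180, 3L))
    P <- diag(rep(sd9^2, n))
  }
  stopifnot(nrow(P) == 9L * n, ncol(P) == 9L * n)
  structure(list(imus = imus, P = P), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state: %d IMUs, P %dx%d, trace %.3e>\n",
              length(x$imus), nrow(x$P), ncol(x$P), sum(diag(x$P))))
  invisible(x)
}

#' Sensor and measurement noise parameters
#'
#' Defaults are the walker study values: accelerometer noise 0.027 m/s^2,
#' gyroscope noise 5.66 deg/s, zero-velocity 0.01 m/s, tilt 5.73 deg,
#' joint-center 0.01 m, joint-axis 1.15 deg, gravity along -z.
#' All stored in SI units (rad, m, s).
#'
#' The joint-axis default deserves a note: the reference noise table
#' nominally lists 1.15 for this entry in radians, but a 66-degree axis
#' constraint is
#' too weak to constrain relative yaw and is irreconcilable with the
#' reported internal/external accuracy, whereas 1.15 degrees reproduces it;
#' the value is therefore interpreted as degrees (see the methods
#' vignette). Pass `sigma_ja = 1.15` to use the literal radian reading.
#'
#' @param sigma_a Accelerometer white-noise SD, m/s^2.
#' @param sigma_w Gyroscope white-noise SD, rad/s.
#' @param sigma_zv Zero-velocity measurement SD, m/s.
#' @param sigma_tilt Gravitational tilt measurement SD, rad.
#' @param sigma_jc Joint-center measurement SD, m.
#' @param sigma_ja Joint-axis measurement SD, rad.
#' @param g World-frame gravity vector, m/s^2.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(sigma_a = 0.027,
                         sigma_w = 5.66 * pi / 180,
                         sigma_zv = 0.01,
                         sigma_tilt = 5.73 * pi / 180,
                         sigma_jc = 0.01,
                         sigma_ja = 1.15 * pi / 180,
                         g = c(0, 0, -9.81)) {
  stopifnot(sigma_a >= 0, sigma_w >= 0, sigma_zv > 0, sigma_tilt > 0,
            sigma_jc > 0, sigma_ja > 0, length(g) == 3L)
  structure(list(sigma_a = sigma_a, sigma_w = sigma_w, sigma_zv = sigma_zv,
                 sigma_tilt = sigma_tilt, sigma_jc = sigma_jc,
                 sigma_ja = sigma_ja, g = as.numeric(g)),
            class = "noise_params")
}

#' Strapdown prediction of one IMU's nominal state
#'
#' Integrates one sampling period of specific force `a` and angular rate `w`
#' (both body frame): position by second-order Taylor step, velocity by the
#' world-frame acceleration `R a + g`, orientation by the exact quaternion
#' increment for a constant rate over `dt`. Independent of all other IMUs.
#'
#' @param x An [imu_state()].
#' @param u List with `a` (m/s^2), `w` (rad/s), `dt` (s).
#' @param g World-frame gravity vector, m/s^2.
#' @return The predicted [imu_state()].
#' @export
predict_state <- function(x, u, g = c(0, 0, -9.81)) {
  if (!all(is.finite(u$a)) || !all(is.finite(u$w)) || !is.finite(u$dt) ||
      u$dt <= 0) {
    stop("predict_state: non-finite or invalid IMU sample (a = ",
         paste(signif(u$a, 3), collapse = ", "), "; w = ",
         paste(signif(u$w, 3), collapse = ", "), "; dt = ", u$dt, ")")
  }
  acc_w <- rotate_vector(x$q, u$a) + g
  p <- x$p + x$v * u$dt + 0.5 * acc_w * u$dt^2
  v <- x$v + acc_w * u$dt
  q <- quat_multiply(x$q, quat_from_rotation_vector(u$w * u$dt))
  imu_state(p, v, q)
}

#' Process-model Jacobian with respect to one IMU's error state
#'
#' The 9x9 block: position rows `[I, dt I, 0]`, velocity rows
#' `[0, I, -R [a]x dt]`, attitude rows `[0, 0, S{w dt}^T]`.
#'
#' @param x An [imu_state()].
#' @param u List with `a`, `w`, `dt`.
#' @return A 9x9 matrix.
#' @export
process_jacobian <- function(x, u) {
  R <- quat_to_matrix(x$q)
  F <- diag(9)
  F[1:3, 4:6] <- diag(3) * u$dt
  F[4:6, 7:9] <- -(R %*% skew(u$a)) * u$dt
  F[7:9, 7:9] <- t(rodrigues(u$w * u$dt))
  F
}

#' Per-IMU process noise covariance
#'
#' `diag(0, sigma_a^2 dt^2 I, sigma_w^2 dt^2 I)`: the position block is
#' exactly zero (position error is driven only through velocity).
#'
#' @param np A [noise_params()] object.
#' @param dt Sampling period, s.
#' @return A 9x9 matrix, constant per trial.
#' @export
process_noise <- function(np, dt) {
  diag(c(rep(0, 3L), rep(np$sigma_a^2 * dt^2, 3L), rep(np$sigma_w^2 * dt^2, 3L)))
}

#' Full-system covariance prediction
#'
#' `P <- F P F^T + Q` with block-diagonal `F` and `Q` assembled from the
#' per-IMU blocks; the result is symmetrized to suppress floating-point
#' asymmetry accumulating over long trials.
#'
#' @param P `9n x 9n` covariance.
#' @param F_blocks List of n 9x9 process Jacobians.
#' @param Q_blocks List of n 9x9 process noise blocks.
#' @return The predicted covariance.
#' @export
predict_covariance <- function(P, F_blocks, Q_blocks) {
  n <- length(F_blocks)
  if (nrow(P) != 9L * n || length(Q_blocks) != n) {
    stop("predict_covariance: dimension mismatch (P is ", nrow(P), "x",
         ncol(P), ", ", n, " F blocks, ", length(Q_blocks), " Q blocks)")
  }
  F <- matrix(0, 9L * n, 9L * n)
  Q <- matrix(0, 9L * n, 9L * n)
  for (j in seq_len(n)) {
    idx <- (9L * (j - 1L) + 1L):(9L * j)
    F[idx, idx] <- F_blocks[[j]]
    Q[idx, idx] <- Q_blocks[[j]]
  }
  P2 <- F %*% P %*% t(F) + Q
  (P2 + t(P2)) / 2
}

#' Jacobian of the nominal state with respect to the error state
#'
#' Block-diagonal `10n x 9n` matrix: identity on position and velocity
#' blocks; the quaternion block is the derivative of the injection
#' `q (x) dq(dtheta)` at `dtheta = 0` (see [dquat_derror()]). Used to chain
#' measurement Jacobians from the nominal state to the error state.
#'
#' @param sys A [system_state()].
#' @return A `10n x 9n` matrix.
#' @export
state_to_errorstate_jacobian <- function(sys) {
  n <- length(sys$imus)
  X <- matrix(0, 10L * n, 9L * n)
  for (j in seq_len(n)) {
    r0 <- 10L * (j - 1L)
    c0 <- 9L * (j - 1L)
    X[r0 + 1:3, c0 + 1:3] <- diag(3)
    X[r0 + 4:6, c0 + 4:6] <- diag(3)
    X[r0 + 7:10, c0 + 7:9] <- dquat_derror(sys$imus[[j]]$q)
  }
  X
}

#' Inject an estimated error into one IMU's nominal state
#'
#' `p <- p + dp`, `v <- v + dv`, `q <- q (x) dq(dtheta)` (renormalized).
#'
#' @param x An [imu_state()].
#' @param dx Numeric length-9 error `(dp, dv, dtheta)`.
#' @return The corrected [imu_state()].
#' @export
inject_error <- function(x, dx) {
  imu_state(x$p + dx[1:3], x$v + dx[4:6],
            quat_multiply(x$q, quat_from_rotation_vector(dx[7:9])))
}

#' Jacobian of the error-state reset for one IMU
#'
#' Identity except the attitude block `I - [dtheta/2]x`, accounting for the
#' reparametrization of the attitude error about the newly corrected
#' orientation after the error mean is reset to zero.
#'
#' @param dtheta Numeric length-3 injected attitude error, rad.
#' @return A 9x9 matrix.
#' @export
reset_jacobian <- function(dtheta) {
  G <- diag(9)
  G[7:9, 7:9] <- diag(3) - skew(dtheta / 2)
  G
}

#' Batch measurement update of the system state
#'
#' Stacks all measurement specs (observations `z`, expectations `h`, sparse
#' Jacobian blocks with respect to the nominal state, noise covariances) into
#' one linear update: `K = P H^T (H P H^T + C)^-1`, `dx = K (z - h)`; the
#' error mean is injected into each nominal IMU state and reset to zero, and
#' the covariance becomes `G (I - K H) P G^T` with the block-diagonal reset
#' Jacobian `G`. The innovation covariance is solved through its Cholesky
#' factorization.
#'
#' @param sys A [system_state()].
#' @param specs Non-empty list of measurement specs (see
#'   [meas_zupt()], [meas_tilt()], [meas_joint_center()], [meas_joint_axis()]).
#' @param cond_limit Abort if the (diagonal-based) condition estimate of the
#'   innovation covariance exceeds this value.
#' @return The updated [system_state()], with the injected error vector in
#'   attribute `"dx"` and the stacked innovation in attribute `"innovation"`.
#' @export
erkf_update <- function(sys, specs, cond_limit = 1e12) {
  if (length(specs) == 0L) stop("erkf_update: no measurement specs supplied")
  n <- length(sys$imus)
  m <- 3L * length(specs)
  P <- sys$P

  # Orientation-block chain factors, computed once per targeted IMU
  Qblocks <- vector("list", n)
  H <- matrix(0, m, 9L * n)
  z <- numeric(m)
  h <- numeric(m)
  Cd <- matrix(0, m, m)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    rows <- (3L * (k - 1L) + 1L):(3L * k)
    z[rows] <- sp$z
    h[rows] <- sp$h
    Cd[rows, rows] <- sp$C
    for (nm in names(sp$H_blocks)) {
      j <- as.integer(nm)
      if (is.null(Qblocks[[j]])) Qblocks[[j]] <- dquat_derror(sys$imus[[j]]$q)
      Hx <- sp$H_blocks[[nm]]               # 3 x 10 w.r.t. nominal state
      c0 <- 9L * (j - 1L)
      H[rows, c0 + 1:6] <- H[rows, c0 + 1:6] + Hx[, 1:6]
      H[rows, c0 + 7:9] <- H[rows, c0 + 7:9] + Hx[, 7:10] %*% Qblocks[[j]]
    }
  }

  PHt <- P %*% t(H)
  S <- H %*% PHt + Cd
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e)
    stop("erkf_update: innovation covariance is numerically singular: ",
         conditionMessage(e)))
  d <- diag(ch)
  if ((max(d) / min(d))^2 > cond_limit) {
    stop("erkf_update: innovation covariance condition estimate exceeds ",
         format(cond_limit))
  }
  K <- PHt %*% chol2inv(ch)
  innov <- z - h
  dx <- as.numeric(K %*% innov)

  imus <- sys$imus
  G <- diag(9L * n)
  for (j in seq_len(n)) {
    idx <- 9L * (j - 1L)
    dxj <- dx[idx + 1:9]
    imus[[j]] <- inject_error(imus[[j]], dxj)
    G[idx + 7:9, idx + 7:9] <- diag(3) - skew(dxj[7:9] / 2)
  }
  Pn <- (diag(9L * n) - K %*% H) %*% P
  Pn <- G %*% Pn %*% t(G)
  Pn <- (Pn + t(Pn)) / 2

  out <- system_state(imus, Pn)
  attr(out, "dx") <- dx
  attr(out, "innovation") <- innov
  out
}

#' Initialize the system state from a still period
#'
#' Orientations are set from the mean accelerometer reading of each IMU over
#' the still samples: the measured gravity direction fixes roll and pitch
#' through the shortest rotation aligning it with world up, leaving yaw at
#' zero for every IMU (global heading is unobservable; relative yaw is
#' recovered by the joint-axis corrections). Positions are chained from the
#' base IMU (placed at `p_anchor`) through the rig's joint centers so every
#' joint-center residual starts at zero; velocities start at zero.
#'
#' @param accel_means List (length n) of mean accelerometer vectors, m/s^2.
#' @param rig A [walker_rig()] describing the joints.
#' @param p_anchor World position assigned to the base IMU.
#' @return A [system_state()] with the default still-start covariance.
#' @export
initialize_state <- function(accel_means, rig, p_anchor = c(0, 0, 0)) {
  n <- length(accel_means)
  qs <- lapply(accel_means, function(a) {
    na <- sqrt(sum(a * a))
    if (na < 1) stop("initialize_state: accelerometer mean too small (",
                     signif(na, 3), " m/s^2) for tilt alignment")
    .shortest_arc(a / na, c(0, 0, 1))
  })
  ps <- vector("list", n)
  base <- rig$base_imu
  ps[[base]] <- as.numeric(p_anchor)
  # breadth-first over joints from the base
  remaining <- rig$joints
  repeat {
    placed <- FALSE
    keep <- list()
    for (jt in remaining) {
      i1 <- jt$imu_a; i2 <- jt$imu_b
      if (!is.null(ps[[i1]]) && is.null(ps[[i2]])) {
        ps[[i2]] <- ps[[i1]] + rotate_vector(qs[[i1]], jt$r_a) -
          rotate_vector(qs[[i2]], jt$r_b)
        placed <- TRUE
      } else if (!is.null(ps[[i2]]) && is.null(ps[[i1]])) {
        ps[[i1]] <- ps[[i2]] + rotate_vector(qs[[i2]], jt$r_b) -
          rotate_vector(qs[[i1]], jt$r_a)
        placed <- TRUE
      } else if (is.null(ps[[i1]]) && is.null(ps[[i2]])) {
        keep <- c(keep, list(jt))
      }
    }
    remaining <- keep
    if (length(remaining) == 0L || !placed) break
  }
  for (j in seq_len(n)) if (is.null(ps[[j]])) ps[[j]] <- c(0, 0, 0)
  system_state(lapply(seq_len(n), function(j) imu_state(ps[[j]], c(0, 0, 0), qs[[j]])))
}

# Shortest-arc quaternion rotating unit vector a onto unit vector b
# (body-to-world when a is a body-frame direction observed as b in world).
.shortest_arc <- function(a, b) {
  d <- sum(a * b)
  if (d < -1 + 1e-12) {
    # antiparallel: rotate half-turn about any axis orthogonal to a
    ax <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * a) * a
    ax <- ax / sqrt(sum(ax * ax))
    return(c(0, ax))
  }
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  quat_normalize(c(1 + d, v))
}
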