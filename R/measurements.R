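# The four kinematic pseudo-measurement models.
#
# Each constructor evaluates, at the current system state, the observation z,
# the expected measurement h(x), the sparse Jacobian H_x with respect to the
# nominal state (3 x 10 blocks keyed by targeted IMU index), and the noise
# covariance C. erkf_update() chains H_x through the state-to-error-state
# Jacobian, so the attitude-block signs here are fixed by the
# right-multiplicative injection convention q (x) dq and are validated by
# finite differences in the test suite.

.meas_spec <- function(kind, z, h, H_blocks, C, targets) {
  structure(list(kind = kind, z = z, h = h, H_blocks = H_blocks, C = C,
                 targets = targets),
            class = "measurement_spec")
}

#' Zero-velocity update (ZUPT) measurement
#'
#' Virtual observation that a momentarily still IMU's velocity is zero:
#' `z = 0`, `h = v_imu`, identity Jacobian on the velocity block.
#'
#' @param sys A [system_state()].
#' @param imu Index of the still IMU.
#' @param sigma_zv Measurement SD, m/s.
#' @return A `measurement_spec`.
#' @export
meas_zupt <- function(sys, imu, sigma_zv) {
  Hx <- matrix(0, 3L, 10L)
  Hx[, 4:6] <- diag(3)
  .meas_spec("zupt", c(0, 0, 0), sys$imus[[imu]]$v,
             stats::setNames(list(Hx), imu),
             diag(3) * sigma_zv^2, imu)
}

#' Gravitational tilt measurement
#'
#' For a still IMU the accelerometer reads pure gravity, so its unit
#' direction observes world "up" expressed in the body frame:
#' `z = a / |a|`, `h = R^T [0, 0, 1]`. Only the direction is compared, not
#' the magnitude, to be robust to residual motion and noise.
#'
#' @param sys A [system_state()].
#' @param imu Index of the still IMU.
#' @param a Measured acceleration, m/s^2 (body frame); rejected if its norm
#'   is below 1 m/s^2 (not gravity-dominated).
#' @param sigma_tilt Measurement SD, rad.
#' @param up World-frame unit vector opposite gravity.
#' @return A `measurement_spec`.
#' @export
meas_tilt <- function(sys, imu, a, sigma_tilt, up = c(0, 0, 1)) {
  na <- sqrt(sum(a * a))
  if (na < 1) {
    stop("meas_tilt: acceleration norm ", signif(na, 3),
         " m/s^2 is not gravity-dominated; rejecting tilt measurement")
  }
  q <- sys$imus[[imu]]$q
  h <- rotate_vector(quat_conjugate(q), up)
  # h = R(q*) up; chain through dq*/dq = diag(1, -1, -1, -1)
  Hq <- drotate_dquat(quat_conjugate(q), up)
  Hq[, 2:4] <- -Hq[, 2:4]
  Hx <- cbind(matrix(0, 3L, 6L), Hq)
  .meas_spec("tilt", a / na, h, stats::setNames(list(Hx), imu),
             diag(3) * sigma_tilt^2, imu)
}

#' Joint-center coincidence measurement
#'
#' The joint center computed from either adjacent IMU must coincide:
#' `h = p1 + R1 r1 - (p2 + R2 r2)`, `z = 0`.
#'
#' @param sys A [system_state()].
#' @param pair Integer length-2: indices of the two adjacent IMUs.
#' @param geom Joint geometry list with `r_a`, `r_b` (offsets from each IMU
#'   to the joint center, in that IMU's frame, m).
#' @param sigma_jc Measurement SD, m.
#' @return A `measurement_spec`.
#' @export
meas_joint_center <- function(sys, pair, geom, sigma_jc) {
  i1 <- pair[1L]; i2 <- pair[2L]
  stopifnot(i1 != i2)
  s1 <- sys$imus[[i1]]; s2 <- sys$imus[[i2]]
  h <- s1$p + rotate_vector(s1$q, geom$r_a) -
    (s2$p + rotate_vector(s2$q, geom$r_b))
  H1 <- cbind(diag(3), matrix(0, 3L, 3L), drotate_dquat(s1$q, geom$r_a))
  H2 <- cbind(-diag(3), matrix(0, 3L, 3L), -drotate_dquat(s2$q, geom$r_b))
  .meas_spec("joint_center", c(0, 0, 0), h,
             stats::setNames(list(H1, H2), c(i1, i2)),
             diag(3) * sigma_jc^2, c(i1, i2))
}

#' Hinge joint-axis alignment measurement
#'
#' The hinge axis expressed in the world frame through either adjacent IMU
#' must coincide: `h = R1 e1 - R2 e2`, `z = 0`.
#'
#' @param sys A [system_state()].
#' @param pair Integer length-2: indices of the two adjacent IMUs.
#' @param geom Joint geometry list with unit axes `e_a`, `e_b` in each IMU's
#'   frame.
#' @param sigma_ja Measurement SD, rad.
#' @return A `measurement_spec`.
#' @export
meas_joint_axis <- function(sys, pair, geom, sigma_ja) {
  i1 <- pair[1L]; i2 <- pair[2L]
  stopifnot(i1 != i2)
  s1 <- sys$imus[[i1]]; s2 <- sys$imus[[i2]]
  h <- rotate_vector(s1$q, geom$e_a) - rotate_vector(s2$q, geom$e_b)
  H1 <- cbind(matrix(0, 3L, 6L), drotate_dquat(s1$q, geom$e_a))
  H2 <- cbind(matrix(0, 3L, 6L), -drotate_dquat(s2$q, geom$e_b))
  .meas_spec("joint_axis", c(0, 0, 0), h,
             stats::setNames(list(H1, H2), c(i1, i2)),
             diag(3) * sigma_ja^2, c(i1, i2))
}

#' Joint geometry between two adjacent IMUs
#'
#' @param imu_a,imu_b Indices of the adjacent IMUs.
#' @param r_a,r_b Offsets from each IMU to the shared joint center, expressed
#'   in that IMU's frame, m.
#' @param e_a,e_b Hinge axis unit vectors in each IMU's frame.
#' @return A list of class `joint_geometry`.
#' @export
joint_geometry <- function(imu_a, imu_b, r_a, r_b, e_a, e_b) {
  e_a <- as.numeric(e_a); e_b <- as.numeric(e_b)
  stopifnot(abs(sqrt(sum(e_a^2)) - 1) < 1e-9, abs(sqrt(sum(e_b^2)) - 1) < 1e-9)
  structure(list(imu_a = as.integer(imu_a), imu_b = as.integer(imu_b),
                 r_a = as.numeric(r_a), r_b = as.numeric(r_b),
                 e_a = e_a, e_b = e_b),
            class = "joint_geometry")
}
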