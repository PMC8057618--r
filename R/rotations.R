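# Quaternion and rotation-vector algebra used throughout the filter.
#
# Quaternions are length-4 numeric vectors stored scalar-first, (w, x, y, z),
# Hamilton convention, and represent body-to-world rotations: a body-frame
# vector y_b maps to the world frame as q (x) [0, y_b] (x) q*.

#' Hamilton product of two quaternions
#'
#' Multiplies two unit quaternions (scalar-first storage) and renormalizes the
#' result to suppress floating-point norm decay.
#'
#' @param q1,q2 Numeric length-4 quaternions, `(w, x, y, z)`.
#' @return A unit quaternion `q1 (x) q2`.
#' @export
#' @examples
#' quat_multiply(c(1, 0, 0, 0), c(0, 1, 0, 0))
quat_multiply <- function(q1, q2) {
  w1 <- q1[1L]; x1 <- q1[2L]; y1 <- q1[3L]; z1 <- q1[4L]
  w2 <- q2[1L]; x2 <- q2[2L]; y2 <- q2[3L]; z2 <- q2[4L]
  q <- c(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
  q / sqrt(sum(q * q))
}

#' Quaternion conjugate (inverse for unit quaternions)
#'
#' @param q Numeric length-4 quaternion.
#' @return The conjugate `(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) c(q[1L], -q[2L], -q[3L], -q[4L])

#' Normalize a quaternion to unit length
#'
#' @param q Numeric length-4 quaternion.
#' @return `q` scaled to unit Euclidean norm.
#' @export
quat_normalize <- function(q) q / sqrt(sum(q * q))

#' Rotation matrix of a unit quaternion
#'
#' Returns the 3x3 direction-cosine matrix R such that `R %*% y_b` equals the
#' world-frame image of the body-frame vector `y_b`.
#'
#' @param q Numeric length-4 unit quaternion.
#' @return A 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3L, byrow = TRUE)
}

#' Rotate a body-frame vector into the world frame
#'
#' Computes the vector part of `q (x) [0, y_b] (x) q*`.
#'
#' @param q Numeric length-4 unit quaternion (body-to-world).
#' @param y Numeric length-3 body-frame vector.
#' @return The world-frame image of `y`; Euclidean norm is preserved.
#' @export
rotate_vector <- function(q, y) {
  # q v q* expanded: v + 2 w (u x v) + 2 u x (u x v), u = vector part
  u <- q[2:4]
  uv <- c(u[2L] * y[3L] - u[3L] * y[2L],
          u[3L] * y[1L] - u[1L] * y[3L],
          u[1L] * y[2L] - u[2L] * y[1L])
  uuv <- c(u[2L] * uv[3L] - u[3L] * uv[2L],
           u[3L] * uv[1L] - u[1L] * uv[3L],
           u[1L] * uv[2L] - u[2L] * uv[1L])
  y + 2 * (q[1L] * uv + uuv)
}

# Threshold below which the exponential map switches to its series expansion.
.small_angle <- 1e-8

#' Exponential map: rotation vector to quaternion
#'
#' Maps a rotation vector `w = phi * s` (angle `phi` about unit axis `s`) to
#' the unit quaternion `(cos(phi/2), s * sin(phi/2))`. For `phi < 1e-8` rad the
#' small-angle form `(1, w/2)` (then normalized) is used, which agrees with the
#' exact map to third order and avoids a 0/0 in the axis.
#'
#' @param w Numeric length-3 rotation vector, radians.
#' @return A unit quaternion.
#' @export
quat_from_rotation_vector <- function(w) {
  phi <- sqrt(sum(w * w))
  if (phi < .small_angle) {
    q <- c(1, w / 2)
    return(q / sqrt(sum(q * q)))
  }
  c(cos(phi / 2), (w / phi) * sin(phi / 2))
}

#' Logarithmic map: quaternion to rotation vector
#'
#' Inverse of [quat_from_rotation_vector()] for rotations with angle below pi.
#' The sign of the scalar part is canonicalized so the returned angle lies in
#' `[0, pi]`.
#'
#' @param q Numeric length-4 unit quaternion.
#' @return Numeric length-3 rotation vector, radians.
#' @export
rotation_vector <- function(q) {
  if (q[1L] < 0) q <- -q
  v <- q[2:4]
  s <- sqrt(sum(v * v))
  if (s < .small_angle) {
    # phi ~ 2 s; axis ~ v / s => w ~ 2 v to leading order
    return(2 * v)
  }
  phi <- 2 * atan2(s, q[1L])
  (v / s) * phi
}

#' Skew-symmetric (cross-product) matrix
#'
#' Returns the 3x3 matrix `[y]x` such that `[y]x %*% v == cross(y, v)`.
#'
#' @param y Numeric length-3 vector.
#' @return A 3x3 antisymmetric matrix.
#' @export
skew <- function(y) {
  matrix(c(0, -y[3L], y[2L],
           y[3L], 0, -y[1L],
           -y[2L], y[1L], 0), nrow = 3L, byrow = TRUE)
}

#' Rodrigues rotation matrix of a rotation vector
#'
#' Evaluates `S{w} = I cos(phi) + sin(phi) [s]x + s s^T (1 - cos(phi))` with
#' `phi = |w|`, `s = w/phi`; returns the identity at `phi = 0`.
#'
#' @param w Numeric length-3 rotation vector, radians.
#' @return A 3x3 rotation matrix (orthogonal, determinant +1).
#' @export
rodrigues <- function(w) {
  phi <- sqrt(sum(w * w))
  if (phi < .small_angle) {
    return(diag(3) + skew(w))
  }
  s <- w / phi
  diag(3) * cos(phi) + sin(phi) * skew(s) + tcrossprod(s) * (1 - cos(phi))
}

#' Derivative of a rotated vector with respect to the quaternion
#'
#' Jacobian of `R(q) %*% y` with respect to the four quaternion components
#' (scalar first), treating `q` as unconstrained. Used to assemble
#' measurement Jacobians with respect to the nominal state.
#'
#' @param q Numeric length-4 unit quaternion.
#' @param y Numeric length-3 body-frame vector.
#' @return A 3x4 matrix.
#' @export
drotate_dquat <- function(q, y) {
  w <- q[1L]; v <- q[2:4]
  vxy <- c(v[2L] * y[3L] - v[3L] * y[2L],
           v[3L] * y[1L] - v[1L] * y[3L],
           v[1L] * y[2L] - v[2L] * y[1L])
  col_w <- 2 * (w * y + vxy)
  block <- 2 * (sum(v * y) * diag(3) + tcrossprod(v, y) - tcrossprod(y, v) -
                  w * skew(y))
  cbind(col_w, block, deparse.level = 0L)
}

#' Quaternion-to-attitude-error Jacobian block
#'
#' Derivative of the injection `q (x) dq(dtheta)` with respect to the small
#' attitude error `dtheta` at `dtheta = 0`: one half times the left-product
#' matrix of `q` applied to the pure-vector basis. This is the orientation
#' block of the state-to-error-state Jacobian.
#'
#' @param q Numeric length-4 unit quaternion.
#' @return A 4x3 matrix.
#' @export
dquat_derror <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  0.5 * matrix(c(
    -x, -y, -z,
     w, -z,  y,
     z,  w, -x,
    -y,  x,  w
  ), nrow = 4L, byrow = TRUE)
}
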