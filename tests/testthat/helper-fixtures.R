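# Shared fixtures and oracles for the suite.

# Deterministic random unit quaternion / vector generators
rand_quat <- function() quat_normalize(stats::rnorm(4L))
rand_vec <- function(scale = 1) stats::rnorm(3L, sd = scale)

# Independent rotation-matrix oracle built from the quaternion components
# (textbook direction-cosine matrix, written out separately from
# quat_to_matrix so the two routes stay independent).
quat_matrix_oracle <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

# Error-state difference between two IMU states: (dp, dv, dtheta) such that
# b = a (+) dx under the right-multiplicative injection.
state_diff <- function(b, a) {
  c(b$p - a$p, b$v - a$v,
    rotation_vector(quat_multiply(quat_conjugate(a$q), b$q)))
}

# Central finite-difference Jacobian of f: R^n -> R^m
fd_jacobian <- function(f, x0, h = 1e-6) {
  m <- length(f(x0))
  J <- matrix(0, m, length(x0))
  for (i in seq_along(x0)) {
    e <- rep(0, length(x0)); e[i] <- h
    J[, i] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
  }
  J
}

# Random small system state with correlated covariance
rand_system <- function(n_imu = 3L) {
  imus <- lapply(seq_len(n_imu), function(j)
    imu_state(rand_vec(), rand_vec(0.3), rand_quat()))
  A <- matrix(stats::rnorm((9 * n_imu)^2, sd = 0.05), 9 * n_imu)
  system_state(imus, crossprod(A) + diag(9 * n_imu) * 1e-4)
}

# Memoised simulation/filter runs shared across test files
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_record <- function(n_strides = 5L, seed = 11L, noisy = FALSE) {
  cached(sprintf("rec_%d_%d_%d", n_strides, seed, noisy),
         simulate_walker(gait_params(n_strides = n_strides, seed = seed),
                         walker_rig(), noise_params(), noisy = noisy))
}

truth_x0 <- function(rec) {
  tr <- rec$truth
  system_state(lapply(c("pelvis", "left_foot", "right_foot"), function(nm)
    imu_state(tr[[nm]]$p[1L, ], tr[[nm]]$v[1L, ], tr[[nm]]$q[1L, ])))
}

# Truth poses repackaged as an erkf_trajectory (perfect estimator)
truth_as_trajectory <- function(rec) {
  imus <- lapply(rec$rig$imu_names, function(nm)
    list(p = rec$truth[[nm]]$p, v = rec$truth[[nm]]$v, q = rec$truth[[nm]]$q))
  names(imus) <- rec$rig$imu_names
  structure(list(t = rec$t, imus = imus, open_loop = FALSE),
            class = "erkf_trajectory")
}

# rotate a constant body-frame vector by each quaternion row
.rot_rows_helper <- function(qm, v) {
  t(apply(qm, 1L, function(q) rotate_vector(q, v)))
}

# Independent dense reference: one textbook EKF-style update on the stacked
# system, with explicit matrix inversion and the same reset-aware
# covariance form, assembled without any package helpers beyond rotations.
dense_update_oracle <- function(sys, specs) {
  n <- length(sys$imus)
  m <- 3L * length(specs)
  Hx <- matrix(0, m, 10L * n)
  z <- numeric(m); h <- numeric(m); C <- matrix(0, m, m)
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    rows <- (3 * (k - 1) + 1):(3 * k)
    z[rows] <- sp$z; h[rows] <- sp$h; C[rows, rows] <- sp$C
    for (nm in names(sp$H_blocks)) {
      j <- as.integer(nm)
      Hx[rows, (10 * (j - 1) + 1):(10 * j)] <-
        Hx[rows, (10 * (j - 1) + 1):(10 * j)] + sp$H_blocks[[nm]]
    }
  }
  X <- state_to_errorstate_jacobian(sys)
  H <- Hx %*% X
  P <- sys$P
  S <- H %*% P %*% t(H) + C
  K <- P %*% t(H) %*% solve(S)
  dx <- as.numeric(K %*% (z - h))
  imus <- lapply(seq_len(n), function(j) {
    xj <- sys$imus[[j]]; d <- dx[(9 * (j - 1) + 1):(9 * j)]
    imu_state(xj$p + d[1:3], xj$v + d[4:6],
              quat_multiply(xj$q, quat_from_rotation_vector(d[7:9])))
  })
  G <- diag(9 * n)
  for (j in seq_len(n)) {
    ii <- (9 * (j - 1) + 7):(9 * j)
    G[ii, ii] <- diag(3) - skew(dx[(9 * (j - 1) + 7):(9 * j)] / 2)
  }
  Pn <- G %*% (diag(9 * n) - K %*% H) %*% P %*% t(G)
  list(imus = imus, P = (Pn + t(Pn)) / 2, dx = dx)
}

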