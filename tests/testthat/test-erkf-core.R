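# Error-state Kalman filter core: prediction, Jacobians, update, reset.

test_that("strapdown prediction handles stillness, uniform motion and constant spin", {
  g <- c(0, 0, -9.81)
  x <- imu_state(q = c(1, 0, 0, 0))
  u <- list(a = c(0, 0, 9.81), w = c(0, 0, 0), dt = 0.1)
  x1 <- predict_state(x, u, g)
  expect_equal(x1$p, c(0, 0, 0))
  expect_equal(x1$v, c(0, 0, 0))
  expect_equal(x1$q, c(1, 0, 0, 0))

  x <- imu_state(v = c(1, 0, 0))
  x1 <- predict_state(x, u, g)
  expect_equal(x1$p, c(0.1, 0, 0))
  expect_equal(x1$v, c(1, 0, 0))

  # constant 1 rad/s yaw for 1000 steps of 1 ms
  x <- imu_state()
  u <- list(a = c(0, 0, 9.81), w = c(0, 0, 1), dt = 1e-3)
  for (k in 1:1000) x <- predict_state(x, u, g)
  expect_equal(rotation_vector(x$q), c(0, 0, 1), tolerance = 1e-6)

  expect_error(predict_state(x, list(a = c(NA, 0, 0), w = c(0, 0, 0), dt = 1e-3), g),
               "non-finite")
})

test_that("process Jacobian has the stated block structure and matches finite differences", {
  dt <- 1 / 512
  x <- imu_state()
  F0 <- process_jacobian(x, list(a = c(0, 0, 0), w = c(0, 0, 0), dt = dt))
  expect_equal(F0[1:3, 1:3], diag(3))
  expect_equal(F0[1:3, 4:6], diag(3) * dt)
  expect_equal(F0[4:6, 7:9], matrix(0, 3, 3))
  expect_equal(F0[7:9, 7:9], diag(3))

  set.seed(13)
  g <- c(0, 0, -9.81)
  for (i in 1:5) {
    x <- imu_state(rand_vec(), rand_vec(), rand_quat())
    u <- list(a = rand_vec(5), w = rand_vec(2), dt = dt)
    F1 <- process_jacobian(x, u)
    expect_equal(F1[7:9, 7:9], t(rodrigues(u$w * dt)))
    Ffd <- fd_jacobian(function(dx)
      state_diff(predict_state(inject_error(x, dx), u, g),
                 predict_state(x, u, g)), rep(0, 9))
    # the stated first-order block structure drops the O(dt^2)
    # position-attitude coupling that exact differentiation of the Taylor
    # prediction carries; augmenting with it, finite differences agree
    Faug <- F1
    Faug[1:3, 7:9] <- F1[4:6, 7:9] * dt / 2
    expect_equal(Faug, Ffd, tolerance = 1e-6)
    expect_lt(max(abs(F1 - Faug)), 10 * dt)   # truncation is O(dt^2 |a|)
  }
})

test_that("process noise follows the stated diagonal structure", {
  dt <- 1 / 512
  Q <- process_noise(noise_params(), dt)
  expect_equal(diag(Q)[1:3], c(0, 0, 0))
  expect_equal(diag(Q)[4:6], rep((0.027 * dt)^2, 3))
  expect_equal(diag(Q)[7:9], rep((5.66 * pi / 180 * dt)^2, 3))
  expect_equal(Q, diag(diag(Q)))
})

test_that("covariance prediction agrees with a dense-matrix oracle", {
  set.seed(17)
  n <- 3L
  sys <- rand_system(n)
  P <- sys$P
  Fb <- lapply(1:n, function(j) matrix(stats::rnorm(81, sd = 0.3), 9, 9) + diag(9))
  Qb <- lapply(1:n, function(j) {
    A <- matrix(stats::rnorm(81, sd = 0.05), 9, 9); crossprod(A)
  })
  got <- predict_covariance(P, Fb, Qb)

  # dense oracle assembled independently
  Fd <- matrix(0, 27, 27); Qd <- matrix(0, 27, 27)
  for (j in 1:n) {
    ii <- (9 * (j - 1) + 1):(9 * j)
    Fd[ii, ii] <- Fb[[j]]; Qd[ii, ii] <- Qb[[j]]
  }
  expect_equal(got, (Fd %*% P %*% t(Fd) + Qd + t(Fd %*% P %*% t(Fd) + Qd)) / 2,
               tolerance = 1e-12)
  # cross-IMU blocks evolve as F_i P_ij F_j^T with no Q coupling
  ij <- got[1:9, 10:18]
  expect_equal(ij, Fb[[1]] %*% P[1:9, 10:18] %*% t(Fb[[2]]), tolerance = 1e-10)

  expect_equal(predict_covariance(P, rep(list(diag(9)), n),
                                  rep(list(matrix(0, 9, 9)), n)), P)
  expect_error(predict_covariance(P[1:18, 1:18], Fb, Qb), "dimension")
})

test_that("state-to-error-state Jacobian matches the injection finite differences", {
  sysI <- system_state(list(imu_state()))
  X <- state_to_errorstate_jacobian(sysI)
  expect_equal(X[1:3, 1:3], diag(3))
  expect_equal(X[4:6, 4:6], diag(3))
  expect_equal(sqrt(colSums(X[7:10, 7:9]^2)), rep(0.5, 3))

  set.seed(19)
  for (i in 1:5) {
    sys <- rand_system(2L)
    X <- state_to_errorstate_jacobian(sys)
    for (j in 1:2) {
      q <- sys$imus[[j]]$q
      Xfd <- fd_jacobian(function(dth)
        quat_multiply(q, quat_from_rotation_vector(dth)), c(0, 0, 0))
      expect_equal(X[(10 * (j - 1) + 7):(10 * j), (9 * (j - 1) + 7):(9 * j)],
                   Xfd, tolerance = 1e-6)
    }
  }
})

test_that("error injection and reset Jacobian behave as specified", {
  x <- imu_state(p = c(1, 2, 3))
  expect_equal(inject_error(x, rep(0, 9)), x)
  xi <- inject_error(imu_state(), c(rep(0, 6), 0, 0, pi / 2))
  expect_equal(rotate_vector(xi$q, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)

  expect_equal(reset_jacobian(c(0, 0, 0)), diag(9))
  G <- reset_jacobian(c(0, 0, 0.2))
  expect_equal(G[7:9, 7:9], diag(3) - skew(c(0, 0, 0.1)))
  set.seed(23)
  for (i in 1:10) {
    dth <- rand_vec(0.3)
    G <- reset_jacobian(dth)
    expect_lte(norm(G - diag(9), "F"),
               0.5 * sqrt(sum(dth^2)) * sqrt(2) + 1e-12)
  }
})

test_that("batch update equals the dense oracle on random 3-IMU systems", {
  set.seed(29)
  rig <- walker_rig()
  np <- noise_params()
  for (i in 1:5) {
    sys <- rand_system(3L)
    specs <- list(
      meas_zupt(sys, 2L, np$sigma_zv),
      meas_tilt(sys, 1L, c(0.3, 0.2, 9.7), np$sigma_tilt),
      meas_joint_center(sys, c(1L, 2L), rig$joints$left, np$sigma_jc),
      meas_joint_axis(sys, c(1L, 3L), rig$joints$right, np$sigma_ja)
    )
    got <- erkf_update(sys, specs)
    want <- dense_update_oracle(sys, specs)
    expect_equal(got$P, want$P, tolerance = 1e-10)
    for (j in 1:3) {
      expect_equal(got$imus[[j]]$p, want$imus[[j]]$p, tolerance = 1e-10)
      expect_equal(got$imus[[j]]$v, want$imus[[j]]$v, tolerance = 1e-10)
      expect_equal(abs(sum(got$imus[[j]]$q * want$imus[[j]]$q)), 1,
                   tolerance = 1e-10)
    }
    # batch result does not depend on the stacking order
    got_rev <- erkf_update(sys, rev(specs))
    expect_equal(got_rev$P, got$P, tolerance = 1e-9)
    expect_equal(got_rev$imus[[1]]$p, got$imus[[1]]$p, tolerance = 1e-9)
  }
})

test_that("zero innovation leaves the state unchanged and shrinks covariance", {
  set.seed(31)
  sys <- rand_system(3L)
  # force a state whose measurements are exactly satisfied: use ZUPT on an
  # IMU with zero velocity
  sys$imus[[2]] <- imu_state(sys$imus[[2]]$p, c(0, 0, 0), sys$imus[[2]]$q)
  upd <- erkf_update(sys, list(meas_zupt(sys, 2L, 0.01)))
  expect_equal(upd$imus[[2]]$p, sys$imus[[2]]$p)
  expect_equal(upd$imus[[2]]$v, c(0, 0, 0))
  expect_equal(upd$imus[[2]]$q, sys$imus[[2]]$q)
  expect_lt(sum(diag(upd$P)), sum(diag(sys$P)) + 1e-12)
})

test_that("exact-measurement limit of ZUPT forces the foot velocity to zero", {
  set.seed(37)
  sys <- rand_system(3L)
  upd <- erkf_update(sys, list(meas_zupt(sys, 3L, 1e-9)))
  expect_equal(upd$imus[[3]]$v, c(0, 0, 0), tolerance = 1e-9)
})

test_that("initialization from a still pose reproduces tilt and joint geometry", {
  rig <- walker_rig()
  # pelvis level in the neutral pose: accelerometer reads +y (superior)
  means <- list(c(0, 9.81, 0), c(0, 9.81, 0), c(0, 9.81, 0))
  sys <- initialize_state(means, rig)
  for (j in 1:3) {
    up_body <- rotate_vector(quat_conjugate(sys$imus[[j]]$q), c(0, 0, 1))
    expect_equal(up_body, c(0, 1, 0), tolerance = 1e-9)
  }
  # joint-center residuals start at zero
  for (jt in rig$joints) {
    r <- sys$imus[[jt$imu_a]]$p +
      rotate_vector(sys$imus[[jt$imu_a]]$q, jt$r_a) -
      sys$imus[[jt$imu_b]]$p -
      rotate_vector(sys$imus[[jt$imu_b]]$q, jt$r_b)
    expect_equal(r, c(0, 0, 0), tolerance = 1e-12)
  }
})
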