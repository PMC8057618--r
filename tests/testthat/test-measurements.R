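# The four measurement models: values, noise, Jacobians, sparsity.

# Chain a spec's nominal-state Jacobian to the error state and compare with
# central finite differences of h evaluated after error injection.
check_spec_jacobian <- function(make_spec, sys, tol = 1e-6) {
  sp <- make_spec(sys)
  n <- length(sys$imus)
  X <- state_to_errorstate_jacobian(sys)
  Hx <- matrix(0, 3L, 10L * n)
  for (nm in names(sp$H_blocks)) {
    j <- as.integer(nm)
    Hx[, (10 * (j - 1) + 1):(10 * j)] <- sp$H_blocks[[nm]]
  }
  H <- Hx %*% X
  Hfd <- fd_jacobian(function(dx) {
    imus2 <- sys$imus
    for (j in seq_len(n)) {
      imus2[[j]] <- inject_error(imus2[[j]], dx[(9 * (j - 1) + 1):(9 * j)])
    }
    make_spec(list(imus = imus2, P = sys$P))$h
  }, rep(0, 9 * n))
  expect_equal(H, Hfd, tolerance = tol)
  # sparsity: columns of untargeted IMUs are exactly zero
  for (j in setdiff(seq_len(n), as.integer(names(sp$H_blocks)))) {
    expect_equal(H[, (9 * (j - 1) + 1):(9 * j)], matrix(0, 3, 9))
  }
  invisible(sp)
}

test_that("ZUPT spec observes velocity with the stated noise", {
  sys <- rand_system(3L)
  sys$imus[[2]] <- imu_state(c(0, 0, 0), c(0.02, -0.01, 0), c(1, 0, 0, 0))
  sp <- meas_zupt(sys, 2L, 0.01)
  expect_equal(sp$z - sp$h, c(-0.02, 0.01, 0))
  expect_equal(sp$C, diag(3) * 1e-4)
  set.seed(41)
  for (i in 1:25) {
    check_spec_jacobian(function(s) meas_zupt(s, 2L, 0.01), rand_system(3L),
                        tol = 1e-7)
  }
})

test_that("tilt spec compares unit gravity directions", {
  sys <- system_state(list(imu_state()))
  sp <- meas_tilt(sys, 1L, c(0, 0, 9.81), 0.1)
  expect_equal(sp$z - sp$h, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(sp$z^2)), 1, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:25) {
    a <- rand_vec(2) + c(0, 0, 9.5)
    sp <- check_spec_jacobian(function(s) meas_tilt(s, 1L, a, 0.1),
                              rand_system(2L), tol = 1e-6)
    expect_equal(sqrt(sum(sp$z^2)), 1, tolerance = 1e-12)
  }
  expect_error(meas_tilt(sys, 1L, c(0.05, 0, 0.1), 0.1), "gravity")
})

test_that("joint-center spec measures joint coincidence", {
  geom <- joint_geometry(1L, 2L, r_a = c(0.1, 0, 0), r_b = c(-0.1, 0, 0),
                         e_a = c(0, 0, 1), e_b = c(0, 0, 1))
  sys <- system_state(list(imu_state(p = c(0, 0, 0)),
                           imu_state(p = c(0.2, 0, 0)),
                           imu_state()))
  sp <- meas_joint_center(sys, c(1L, 2L), geom, 0.01)
  expect_equal(sp$h, c(0, 0, 0), tolerance = 1e-12)

  set.seed(47)
  for (i in 1:25) {
    sys <- rand_system(3L)
    sp <- check_spec_jacobian(function(s)
      meas_joint_center(s, c(1L, 3L), geom, 0.01), sys, tol = 1e-6)
    # |h| equals the distance between the two predicted joint positions
    j1 <- sys$imus[[1]]$p + rotate_vector(sys$imus[[1]]$q, geom$r_a)
    j2 <- sys$imus[[3]]$p + rotate_vector(sys$imus[[3]]$q, geom$r_b)
    expect_equal(sqrt(sum(sp$h^2)), sqrt(sum((j1 - j2)^2)), tolerance = 1e-12)
  }
})

test_that("joint-axis spec measures hinge-axis misalignment", {
  geom <- joint_geometry(1L, 2L, r_a = c(0, 0, 0.2), r_b = c(0, 0.9, 0),
                         e_a = c(0, 0, 1), e_b = c(0, 0, 1))
  sys <- system_state(list(imu_state(), imu_state(), imu_state()))
  sp <- meas_joint_axis(sys, c(1L, 2L), geom, 0.02)
  expect_equal(sp$h, c(0, 0, 0), tolerance = 1e-12)

  # chord-length identity: axes misaligned by alpha give |h| = 2 sin(alpha/2)
  set.seed(53)
  for (alpha in c(0.1, 0.5, 1.2)) {
    q2 <- quat_from_rotation_vector(c(alpha, 0, 0))  # perpendicular to e = z
    sys2 <- system_state(list(imu_state(), imu_state(q = q2), imu_state()))
    sp2 <- meas_joint_axis(sys2, c(1L, 2L), geom, 0.02)
    expect_equal(sqrt(sum(sp2$h^2)), 2 * sin(alpha / 2), tolerance = 1e-12)
  }
  for (i in 1:25) {
    check_spec_jacobian(function(s) meas_joint_axis(s, c(2L, 3L), geom, 0.02),
                        rand_system(3L), tol = 1e-6)
  }
})

test_that("innovations vanish on ground-truth simulator states", {
  rec <- small_record(2L)
  rig <- rec$rig
  np <- noise_params()
  set.seed(59)
  for (k in sort(sample(length(rec$t), 20L))) {
    sys <- list(imus = lapply(rig$imu_names, function(nm)
      imu_state(rec$truth[[nm]]$p[k, ], rec$truth[[nm]]$v[k, ],
                rec$truth[[nm]]$q[k, ])))
    for (jt in rig$joints) {
      spc <- meas_joint_center(sys, c(jt$imu_a, jt$imu_b), jt, np$sigma_jc)
      expect_equal(spc$z - spc$h, c(0, 0, 0), tolerance = 1e-10)
      spa <- meas_joint_axis(sys, c(jt$imu_a, jt$imu_b), jt, np$sigma_ja)
      expect_equal(spa$z - spa$h, c(0, 0, 0), tolerance = 1e-10)
    }
  }
  # ZUPT and tilt at a still sample (first still window)
  k <- 5L
  sys <- list(imus = lapply(rig$imu_names, function(nm)
    imu_state(rec$truth[[nm]]$p[k, ], rec$truth[[nm]]$v[k, ],
              rec$truth[[nm]]$q[k, ])))
  for (j in 1:3) {
    spz <- meas_zupt(sys, j, np$sigma_zv)
    expect_equal(spz$z - spz$h, c(0, 0, 0), tolerance = 1e-12)
    spt <- meas_tilt(sys, j, rec$imu_ideal[[j]]$a[k, ], np$sigma_tilt)
    expect_equal(spt$z - spt$h, c(0, 0, 0), tolerance = 1e-10)
  }
})
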