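# Event detection, hip angles, spatiotemporal metrics, comparison stats.

test_that("still-period detection recovers the annotated windows on clean data", {
  rec <- small_record(3L)
  for (f in c("left", "right")) {
    foot <- paste0(f, "_foot")
    got <- detect_still_periods(rec$imu_ideal[[foot]]$w,
                                rec$imu_ideal[[foot]]$a, rec$t,
                                min_duration = 0.09)
    want <- rec$events[rec$events$foot == f, , drop = FALSE]
    # every annotated window lies inside exactly one detected window; the
    # detected window may start/end slightly outside it because the smooth
    # waveform crosses the 2 deg/s rate threshold shortly before contact
    # and shortly after the window ends (~55 ms for the default gait)
    for (i in seq_len(nrow(want))) {
      j <- which(got$t_start <= want$t_still_start[i] + rec$dt &
                   got$t_end >= want$t_still_end[i] - 2 * rec$dt)
      expect_length(j, 1L)
      expect_lt(want$t_still_start[i] - got$t_start[j], 0.1)
      expect_lt(got$t_end[j] - want$t_still_end[i], 0.1)
    }
    # tightening the rate threshold shrinks the takeoff margin towards the
    # annotated boundaries
    tight <- detect_still_periods(rec$imu_ideal[[foot]]$w,
                                  rec$imu_ideal[[foot]]$a, rec$t,
                                  w_thresh = 0.1 * pi / 180,
                                  min_duration = 0.09)
    for (i in seq_len(nrow(want))) {
      j <- which.min(abs(tight$t_start - want$t_still_start[i]))
      expect_lt(abs(tight$t_start[j] - want$t_still_start[i]), 0.02)
      expect_lt(abs(tight$t_end[j] - want$t_still_end[i]), 0.02)
    }
  }
  # constant-rate spinning stream: no windows
  n <- 1000L; tt <- (0:(n - 1)) / 512
  spin_w <- matrix(rep(c(0, 0, 1), each = n), n, 3L)
  grav <- matrix(rep(c(0, 0, 9.81), each = n), n, 3L)
  expect_equal(nrow(detect_still_periods(spin_w, grav, tt)), 0L)
  # all-stationary stream: one window spanning the trial
  still <- detect_still_periods(matrix(0, n, 3L), grav, tt)
  expect_equal(nrow(still), 1L)
  expect_equal(c(still$t_start, still$t_end), c(0, tt[n]))
})

test_that("footfalls are window midpoints, ordered", {
  expect_equal(detect_footfalls(data.frame(t_start = 10.0, t_end = 10.1)),
               10.05)
  expect_equal(detect_footfalls(data.frame(t_start = numeric(),
                                           t_end = numeric())), numeric(0))
  rec <- small_record(5L)
  for (f in c("left", "right")) {
    w <- rec$events[rec$events$foot == f, , drop = FALSE]
    ff <- detect_footfalls(data.frame(t_start = w$t_still_start,
                                      t_end = w$t_still_end))
    expect_equal(length(ff), nrow(w))
    expect_true(all(diff(ff) > 0))
  }
})

test_that("hip angle decomposition handles identity, hinge and mirroring", {
  qI <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(unlist(hip_angles(qI, qI, "right")[1, 1:3]),
               c(flexion = 0, adduction = 0, internal = 0))
  q30 <- matrix(quat_from_rotation_vector(c(0, 0, pi / 6)), 1, 4)
  a <- hip_angles(qI, q30, "right")
  expect_equal(a$flexion, 30, tolerance = 1e-10)
  expect_equal(a$adduction, 0, tolerance = 1e-10)
  expect_equal(a$internal, 0, tolerance = 1e-10)
  # flexion sign is shared between sides; the other two mirror
  qad <- matrix(quat_from_rotation_vector(c(0.2, 0, 0)), 1, 4)
  r <- hip_angles(qI, qad, "right"); l <- hip_angles(qI, qad, "left")
  expect_equal(r$adduction, -l$adduction)
  qint <- matrix(quat_from_rotation_vector(c(0, 0.2, 0)), 1, 4)
  r <- hip_angles(qI, qint, "right"); l <- hip_angles(qI, qint, "left")
  expect_equal(r$internal, -l$internal)
})

test_that("angle unwrap leaves no jumps above 180 degrees", {
  tt <- seq(0, 20, by = 1 / 64)
  qm <- t(vapply(tt, function(x)
    quat_from_rotation_vector(c(0, 0, 0.9 * pi * sin(0.4 * x))), numeric(4L)))
  ang <- hip_angles(matrix(c(1, 0, 0, 0), length(tt), 4L, byrow = TRUE), qm,
                    "right")
  expect_lt(max(abs(diff(ang$flexion))), 180)
  # and reproduces the smooth prescribed angle
  expect_equal(ang$flexion, 0.9 * 180 * sin(0.4 * tt), tolerance = 1e-8)
})

test_that("stride metrics recover constructed geometry and are yaw-invariant", {
  # constructed: walk along x, feet at +/- 0.195 m laterally, contacts on a
  # regular grid
  tt <- seq(0, 10, by = 0.01)
  n <- length(tt)
  xl <- 0.4 * tt; xr <- 0.4 * tt
  pos_l <- cbind(xl, 0.195, 0)
  pos_r <- cbind(xr, -0.195, 0)
  ffl <- seq(1, 9, by = 1)
  ffr <- seq(0.5, 9.5, by = 1)
  sm <- stride_metrics(tt, pos_l, pos_r, ffl, ffr,
                       exclude_transition = FALSE)
  expect_equal(sm$strides$stride_length,
               rep(0.4, nrow(sm$strides)), tolerance = 1e-12)
  expect_equal(sm$steps$width, rep(0.39, nrow(sm$steps)), tolerance = 1e-12)
  expect_true(all(sm$strides$straight))

  # invariance to world yaw + translation
  yaw <- 0.83
  Rz <- rodrigues(c(0, 0, yaw))
  shift <- c(5, -3, 0.2)
  rot <- function(p) sweep(p %*% t(Rz), 2L, -shift)
  sm2 <- stride_metrics(tt, rot(pos_l), rot(pos_r), ffl, ffr,
                        exclude_transition = FALSE)
  expect_equal(sm2$strides$stride_length, sm$strides$stride_length,
               tolerance = 1e-10)
  expect_equal(sm2$steps$width, sm$steps$width, tolerance = 1e-10)

  expect_error(stride_metrics(tt, pos_l, pos_r, numeric(0), 5), "footfalls")
})

test_that("simulator ground truth yields the prescribed stride length and width", {
  rec <- small_record(5L)
  ev <- rec$events
  ff <- lapply(c(left = "left", right = "right"), function(f) {
    w <- ev[ev$foot == f, ]
    detect_footfalls(data.frame(t_start = w$t_still_start,
                                t_end = w$t_still_end))
  })
  sm <- stride_metrics(rec$t, rec$truth$left_foot$p, rec$truth$right_foot$p,
                       ff$left, ff$right, sacrum = rec$truth$pelvis$p)
  expect_equal(mean(sm$strides$stride_length), 0.73, tolerance = 1e-9)
  expect_equal(mean(sm$steps$width), 0.39, tolerance = 1e-9)
})

test_that("comparison statistics match closed forms", {
  x <- seq(0, 1, length.out = 1000L)
  cs <- compare_series(x, x, x)
  expect_equal(cs$mean_diff, 0)
  expect_equal(cs$rms_diff, 0)
  expect_equal(cs$drift_slope, 0)

  cs <- compare_series(x + 0.5, x, x)
  expect_equal(cs$mean_diff, 0.5)
  expect_equal(cs$sd_diff, 0)
  expect_equal(cs$rms_diff, 0.5)

  tt <- seq(0, 200, by = 1 / 64)
  d <- 0.1 * sin(2 * pi * tt / 2)
  cs <- compare_series(d, rep(0, length(d)), tt)
  expect_equal(cs$rms_diff, 0.1 / sqrt(2), tolerance = 1e-4)
  # rms^2 = mean^2 + sd^2 (n-1)/n
  n <- cs$n
  expect_equal(cs$rms_diff^2,
               cs$mean_diff^2 + cs$sd_diff^2 * (n - 1) / n, tolerance = 1e-12)
  # drift slope in units per hour
  cs <- compare_series(0.001 * tt, rep(0, length(tt)), tt)
  expect_equal(cs$drift_slope, 3.6, tolerance = 1e-9)

  expect_error(compare_series(1:5, 1:4), "lengths")
})

test_that("range-of-motion differences are computed per stride", {
  tt <- seq(0, 10, by = 0.01)
  ref <- 10 * sin(2 * pi * tt)         # ROM 20 per cycle
  est <- 11 * sin(2 * pi * tt)         # ROM 22 per cycle
  wins <- data.frame(t_start = 0:8, t_end = 1:9)
  cs <- compare_series(est, ref, tt, stride_windows = wins)
  expect_equal(cs$rom_mean_diff, 2, tolerance = 1e-6)
  expect_equal(cs$rom_rms_diff, 2, tolerance = 1e-6)
  expect_true(all(cs$rom$rom_ref >= 0))
})

test_that("Bland-Altman limits match the Monte-Carlo oracle", {
  expect_error(bland_altman(1, 1), "2 paired")
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$mean_diff, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))

  set.seed(61)
  ref <- stats::rnorm(1e5)
  est <- ref + stats::rnorm(1e5, mean = 0.5, sd = 1)
  ba <- bland_altman(est, ref)
  expect_equal(ba$mean_diff, 0.5, tolerance = 0.02)
  expect_equal(ba$loa_lower, 0.5 - 1.96, tolerance = 0.02)
  expect_equal(ba$loa_upper, 0.5 + 1.96, tolerance = 0.02)

  flip <- bland_altman(ref, est)
  expect_equal(flip$mean_diff, -ba$mean_diff)
  expect_equal(flip$loa_lower, -ba$loa_upper)
  expect_equal(flip$loa_upper, -ba$loa_lower)
})
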