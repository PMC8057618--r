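# Time loop binding prediction and batch measurement updates.

#' Measurement schedule for a trial
#'
#' Describes when each correction applies. Joint-center and joint-axis
#' corrections apply at every sample (the hips are permanent hinges here);
#' ZUPT and tilt apply inside the annotated still windows. By default ZUPT
#' targets the foot owning the window while tilt targets all IMUs, because
#' the walker pauses entirely during each still period; both choices are
#' configurable, as is collapsing ZUPT to the single footfall instant.
#'
#' @param events Data frame with columns `foot` ("left"/"right"),
#'   `t_contact`, `t_still_start`, `t_still_end` (s).
#' @param enable Character vector among
#'   `c("zupt", "tilt", "joint_center", "joint_axis")`.
#' @param zupt_mode `"window"` (every sample in the still window) or
#'   `"instant"` (single sample nearest the footfall).
#' @param zupt_targets `"all_feet"` (both feet during every still window --
#'   the walker pauses entirely, so an event-identification pass marks both
#'   feet still) or `"owner"` (only the foot whose contact opened the
#'   window).
#' @param tilt_targets `"all"` (every IMU during a still window) or
#'   `"owner"` (the contacting foot only).
#' @return A list of class `measurement_schedule`.
#' @export
measurement_schedule <- function(events,
                                 enable = c("zupt", "tilt", "joint_center",
                                            "joint_axis"),
                                 zupt_mode = c("window", "instant"),
                                 zupt_targets = c("all_feet", "owner"),
                                 tilt_targets = c("all", "owner")) {
  zupt_mode <- match.arg(zupt_mode)
  zupt_targets <- match.arg(zupt_targets)
  tilt_targets <- match.arg(tilt_targets)
  bad <- setdiff(enable, c("zupt", "tilt", "joint_center", "joint_axis"))
  if (length(bad)) stop("measurement_schedule: unknown corrections: ",
                        paste(bad, collapse = ", "))
  structure(list(events = events, enable = enable, zupt_mode = zupt_mode,
                 zupt_targets = zupt_targets, tilt_targets = tilt_targets),
            class = "measurement_schedule")
}

# Boolean per-sample activity masks (n x n_imu) for ZUPT and tilt.
.schedule_masks <- function(schedule, t, rig) {
  n <- length(t)
  n_imu <- length(rig$imu_names)
  zupt <- matrix(FALSE, n, n_imu)
  tilt <- matrix(FALSE, n, n_imu)
  ev <- schedule$events
  foot_idx <- match(paste0(ev$foot, "_foot"), rig$imu_names)
  feet <- grep("_foot$", rig$imu_names)
  zupt_default <- is.null(schedule$zupt_targets)
  for (i in seq_len(nrow(ev))) {
    j <- foot_idx[i]
    jz <- if (zupt_default || schedule$zupt_targets == "all_feet") feet else j
    inwin <- t >= ev$t_still_start[i] - 1e-9 & t <= ev$t_still_end[i] + 1e-9
    if ("zupt" %in% schedule$enable) {
      if (schedule$zupt_mode == "window") {
        zupt[inwin, jz] <- TRUE
      } else {
        zupt[which.min(abs(t - ev$t_contact[i])), jz] <- TRUE
      }
    }
    if ("tilt" %in% schedule$enable) {
      if (schedule$tilt_targets == "all") tilt[inwin, ] <- TRUE
      else tilt[inwin, j] <- TRUE
    }
  }
  list(zupt = zupt, tilt = tilt)
}

#' Run the multi-IMU error-state Kalman filter over a trial
#'
#' For each sample: apply the batch measurement update due at that instant
#' (canonical order: ZUPT, tilt, joint-center, joint-axis; left before
#' right), log the corrected state, then strapdown-predict every IMU and
#' propagate the joint covariance to the next sample.
#'
#' @param imu `imu_signals`: per-IMU list with `a`, `w` (n x 3 matrices).
#' @param t Sample times, s (constant rate).
#' @param rig A [walker_rig()].
#' @param np A [noise_params()].
#' @param schedule A [measurement_schedule()]; pass `enable = character(0)`
#'   for an open-loop (pure integration) run.
#' @param x0 Initial [system_state()]; if `NULL`, initialized from the first
#'   annotated still window via [initialize_state()].
#' @param gyro_bias_correction Optional list of per-IMU constant gyro biases
#'   (rad/s) subtracted from the incoming samples (pre-estimated biases are
#'   treated as known; they are not part of the state).
#' @param diag_every Record covariance diagnostics (minimum eigenvalue,
#'   asymmetry, trace) every this many steps; 0 disables.
#' @return A list of class `erkf_trajectory`: `t`; per-IMU `p`, `v` (n x 3),
#'   `q` (n x 4); `n_meas` (measurement rows per step); `innov_norm`;
#'   `diagnostics` data.frame; `open_loop` flag.
#' @export
run_filter <- function(imu, t, rig, np, schedule, x0 = NULL,
                       gyro_bias_correction = NULL, diag_every = 5000L) {
  n_imu <- length(setdiff(names(imu), "t"))
  imu <- imu[setdiff(names(imu), "t")]
  n <- length(t)
  lens <- vapply(imu, function(s) nrow(s$a), integer(1L))
  if (any(lens != n)) {
    stop("run_filter: IMU stream lengths (", paste(lens, collapse = ", "),
         ") do not match the time base (", n, " samples)")
  }
  dt <- t[2L] - t[1L]
  if (!is.null(gyro_bias_correction)) {
    for (j in seq_len(n_imu)) {
      imu[[j]]$w <- imu[[j]]$w -
        matrix(gyro_bias_correction[[j]], n, 3L, byrow = TRUE)
    }
  }
  masks <- .schedule_masks(schedule, t, rig)
  do_jc <- "joint_center" %in% schedule$enable
  do_ja <- "joint_axis" %in% schedule$enable
  joints <- rig$joints[order(names(rig$joints))]   # left before right

  if (is.null(x0)) {
    ev1 <- schedule$events[1L, ]
    init_idx <- which(t >= ev1$t_still_start - 1e-9 & t <= ev1$t_still_end + 1e-9)
    if (length(init_idx) < 1L) init_idx <- 1:min(8L, n)
    means <- lapply(imu, function(s)
      colMeans(s$a[init_idx, , drop = FALSE]))
    x0 <- initialize_state(means, rig)
  }

  sys <- x0
  qproc <- rep(c(rep(0, 3L), rep(np$sigma_a^2 * dt^2, 3L),
                 rep(np$sigma_w^2 * dt^2, 3L)), n_imu)
  Fm <- diag(9L * n_imu)
  for (j in seq_len(n_imu)) {
    idx <- 9L * (j - 1L)
    Fm[idx + 1:3, idx + 4:6] <- diag(3) * dt
  }

  P <- sys$P
  imus <- sys$imus
  traj <- lapply(seq_len(n_imu), function(j)
    list(p = matrix(NA_real_, n, 3L), v = matrix(NA_real_, n, 3L),
         q = matrix(NA_real_, n, 4L)))
  n_meas <- integer(n)
  innov_norm <- numeric(n)
  diag_rows <- list()

  for (k in seq_len(n)) {
    # ----- batch measurement update -----
    specs <- list()
    for (j in seq_len(n_imu)) if (masks$zupt[k, j]) {
      specs[[length(specs) + 1L]] <-
        meas_zupt(list(imus = imus), j, np$sigma_zv)
    }
    for (j in seq_len(n_imu)) if (masks$tilt[k, j]) {
      a_k <- imu[[j]]$a[k, ]
      if (sqrt(sum(a_k^2)) >= 1) {
        specs[[length(specs) + 1L]] <-
          meas_tilt(list(imus = imus), j, a_k, np$sigma_tilt)
      }
    }
    if (do_jc) {
      for (jt in joints) {
        specs[[length(specs) + 1L]] <-
          meas_joint_center(list(imus = imus), c(jt$imu_a, jt$imu_b), jt,
                            np$sigma_jc)
      }
    }
    if (do_ja) {
      for (jt in joints) {
        specs[[length(specs) + 1L]] <-
          meas_joint_axis(list(imus = imus), c(jt$imu_a, jt$imu_b), jt,
                          np$sigma_ja)
      }
    }
    if (length(specs)) {
      upd <- erkf_update(system_state(imus, P), specs)
      imus <- upd$imus
      P <- upd$P
      n_meas[k] <- 3L * length(specs)
      innov_norm[k] <- sqrt(sum(attr(upd, "innovation")^2))
    }

    for (j in seq_len(n_imu)) {
      traj[[j]]$p[k, ] <- imus[[j]]$p
      traj[[j]]$v[k, ] <- imus[[j]]$v
      traj[[j]]$q[k, ] <- imus[[j]]$q
    }
    if (diag_every > 0L && (k %% diag_every == 1L || k == n)) {
      ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
      diag_rows[[length(diag_rows) + 1L]] <-
        c(step = k, min_eig = min(ev), asym = max(abs(P - t(P))),
          trace = sum(diag(P)))
    }
    if (k == n) break

    # ----- prediction -----
    for (j in seq_len(n_imu)) {
      u <- list(a = imu[[j]]$a[k, ], w = imu[[j]]$w[k, ], dt = dt)
      xj <- imus[[j]]
      R <- quat_to_matrix(xj$q)
      idx <- 9L * (j - 1L)
      Fm[idx + 4:6, idx + 7:9] <- -(R %*% skew(u$a)) * dt
      Fm[idx + 7:9, idx + 7:9] <- t(rodrigues(u$w * dt))
      acc_w <- as.numeric(R %*% u$a) + np$g
      p_new <- xj$p + xj$v * dt + 0.5 * acc_w * dt^2
      v_new <- xj$v + acc_w * dt
      q_new <- quat_multiply(xj$q, quat_from_rotation_vector(u$w * dt))
      if (!all(is.finite(p_new)) || !all(is.finite(q_new))) {
        stop("run_filter: non-finite state at step ", k, " (IMU ", j, ")")
      }
      imus[[j]] <- structure(list(p = p_new, v = v_new, q = q_new),
                             class = "imu_state")
    }
    P <- Fm %*% P %*% t(Fm)
    dP <- diag(P) + qproc
    diag(P) <- dP
    P <- (P + t(P)) / 2
  }

  diagnostics <- if (length(diag_rows))
    as.data.frame(do.call(rbind, diag_rows)) else
      data.frame(step = integer(), min_eig = numeric(), asym = numeric(),
                 trace = numeric())
  names(traj) <- names(imu)
  structure(list(t = t, imus = traj, n_meas = n_meas,
                 innov_norm = innov_norm, diagnostics = diagnostics,
                 open_loop = length(schedule$enable) == 0L,
                 final_state = system_state(imus, P)),
            class = "erkf_trajectory")
}

#' @export
print.erkf_trajectory <- function(x, ...) {
  cat(sprintf(
    "<erkf_trajectory: %d IMUs, %d samples%s, %d measurement rows applied>\n",
    length(x$imus), length(x$t), if (x$open_loop) " (open-loop)" else "",
    sum(x$n_meas)))
  invisible(x)
}

#' Segment orientation series from an estimated trajectory
#'
#' Removes each IMU's mount rotation so the returned quaternions describe
#' the host segments.
#'
#' @param traj An `erkf_trajectory`.
#' @param rig The [walker_rig()] used for the run.
#' @return List per IMU of n x 4 segment quaternion matrices.
#' @export
segment_orientations <- function(traj, rig) {
  out <- lapply(seq_along(traj$imus), function(j) {
    qm <- traj$imus[[j]]$q
    mq <- rig$imu_mounts[[j]]$q
    if (all(mq == c(1, 0, 0, 0))) return(qm)
    .qmult_rows(qm, quat_conjugate(mq))
  })
  names(out) <- names(traj$imus)
  out
}
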