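# Trial-level analysis and the simulate / filter / analyze pipeline with
# CSV/YAML/JSON interchange.

#' Full accuracy report for one walker trial
#'
#' Compares a filter trajectory against the ground truth of the same trial:
#' per-sample hip joint angle differences (both hips, three angles each,
#' ISB decomposition applied identically to estimate and truth), per-stride
#' flexion/extension range of motion, drift slopes of the angle differences,
#' and stride-length / step-width differences. Samples and strides inside
#' each leg's first (transition) stride are excluded.
#'
#' @param record The `gait_record` the filter ran on.
#' @param traj The `erkf_trajectory` returned by [run_filter()].
#' @param exclude_transition Exclude each leg's first stride.
#' @return A list of class `gait_report`; see Details.
#' @details Fields: `angles` (per side, per angle [compare_series()]
#'   results), `summary` (data.frame keyed flexion/internal/abduction with
#'   mean/sd/rms and flexion ROM stats, pooled across hips), `drift`
#'   (deg/hr per angle, right hip), `stride_stats`, `step_stats`
#'   (mean/sd/rms differences in m and % of the true means), `strides_est`,
#'   `strides_true` (stride tables), `footfalls` (per foot).
#' @export
analyze_trial <- function(record, traj, exclude_transition = TRUE) {
  rig <- record$rig
  t <- record$t
  est_q <- segment_orientations(traj, rig)
  true_q <- lapply(seq_along(rig$imu_names), function(j) {
    qm <- record$truth[[rig$imu_names[j]]]$q
    mq <- rig$imu_mounts[[j]]$q
    if (all(mq == c(1, 0, 0, 0))) qm else .qmult_rows(qm, quat_conjugate(mq))
  })
  names(true_q) <- rig$imu_names

  ev <- record$events
  ff <- lapply(c(left = "left", right = "right"), function(f) {
    w <- ev[ev$foot == f, , drop = FALSE]
    detect_footfalls(data.frame(t_start = w$t_still_start,
                                t_end = w$t_still_end))
  })

  sides <- c("left", "right")
  angles <- list()
  angle_names <- c("flexion", "internal", "adduction")
  for (s in sides) {
    leg_imu <- paste0(s, "_foot")
    ae <- hip_angles(est_q$pelvis, est_q[[leg_imu]], side = s)
    at <- hip_angles(true_q$pelvis, true_q[[leg_imu]], side = s)
    f <- ff[[s]]
    lo <- if (exclude_transition && length(f) >= 2L) f[2L] else f[1L]
    hi <- f[length(f)]
    idx <- t >= lo - 1e-9 & t <= hi + 1e-9
    wins <- data.frame(t_start = f[-length(f)], t_end = f[-1L])
    if (exclude_transition && nrow(wins) >= 1L) wins <- wins[-1L, , drop = FALSE]
    angles[[s]] <- list(
      est = ae, true = at, idx = idx, windows = wins,
      stats = lapply(stats::setNames(angle_names, angle_names), function(an) {
        compare_series(ae[[an]][idx], at[[an]][idx], t[idx],
                       stride_windows = if (an == "flexion") wins else NULL)
      })
    )
  }

  # pooled across both hips, per angle
  pooled <- lapply(stats::setNames(angle_names, angle_names), function(an) {
    d <- unlist(lapply(sides, function(s) {
      a <- angles[[s]]
      a$est[[an]][a$idx] - a$true[[an]][a$idx]
    }))
    c(mean = mean(d), sd = stats::sd(d), rms = sqrt(mean(d^2)))
  })
  romd <- unlist(lapply(sides, function(s) {
    r <- angles[[s]]$stats$flexion$rom
    if (is.null(r)) return(numeric(0L))
    r$rom_est - r$rom_ref
  }))
  romd <- romd[is.finite(romd)]
  summary <- data.frame(
    angle = c("flexion", "internal", "abduction"),
    mean = c(pooled$flexion["mean"], pooled$internal["mean"],
             pooled$adduction["mean"]),
    sd = c(pooled$flexion["sd"], pooled$internal["sd"], pooled$adduction["sd"]),
    rms = c(pooled$flexion["rms"], pooled$internal["rms"],
            pooled$adduction["rms"]),
    rom_mean = c(mean(romd), NA, NA),
    rom_sd = c(stats::sd(romd), NA, NA),
    rom_rms = c(sqrt(mean(romd^2)), NA, NA),
    row.names = NULL
  )

  drift <- vapply(angle_names, function(an)
    angles$right$stats[[an]]$drift_slope, numeric(1L))
  names(drift) <- c("flexion", "internal", "abduction")

  # spatiotemporal metrics: same footfall times for estimate and truth,
  # positions from each source
  sm_est <- stride_metrics(t, traj$imus$left_foot$p, traj$imus$right_foot$p,
                           ff$left, ff$right, sacrum = traj$imus$pelvis$p,
                           exclude_transition = exclude_transition)
  sm_true <- stride_metrics(t, record$truth$left_foot$p,
                            record$truth$right_foot$p,
                            ff$left, ff$right,
                            sacrum = record$truth$pelvis$p,
                            exclude_transition = exclude_transition)
  sd_diff <- sm_est$strides$stride_length - sm_true$strides$stride_length
  sw_diff <- sm_est$steps$width - sm_true$steps$width
  stride_stats <- list(mean = mean(sd_diff), sd = stats::sd(sd_diff),
                       rms = sqrt(mean(sd_diff^2)),
                       rms_pct = 100 * sqrt(mean(sd_diff^2)) /
                         mean(sm_true$strides$stride_length),
                       n = length(sd_diff))
  step_stats <- list(mean = mean(sw_diff), sd = stats::sd(sw_diff),
                     rms = sqrt(mean(sw_diff^2)),
                     rms_pct = 100 * sqrt(mean(sw_diff^2)) /
                       mean(sm_true$steps$width),
                     n = length(sw_diff))

  structure(list(angles = angles, summary = summary, drift = drift,
                 stride_stats = stride_stats, step_stats = step_stats,
                 strides_est = sm_est$strides, strides_true = sm_true$strides,
                 steps_est = sm_est$steps, steps_true = sm_true$steps,
                 footfalls = ff),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("Hip joint angle differences, pooled across hips (deg):\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  cat(sprintf("Drift slopes (right hip, deg/hr): %s\n",
              paste(sprintf("%s %.3g", names(x$drift), x$drift),
                    collapse = ", ")))
  cat(sprintf("Stride length: RMS diff %.4f m (%.2f%%), n = %d\n",
              x$stride_stats$rms, x$stride_stats$rms_pct, x$stride_stats$n))
  cat(sprintf("Step width:    RMS diff %.4f m (%.2f%%), n = %d\n",
              x$step_stats$rms, x$step_stats$rms_pct, x$step_stats$n))
  invisible(x)
}

#' Per-stride ensemble of a series over the normalized gait cycle
#'
#' Resamples a series onto `n_points` of the normalized gait cycle for each
#' stride window and returns the across-stride mean and SD curves.
#'
#' @param x Numeric series.
#' @param t Sample times, s.
#' @param windows Data frame with `t_start`, `t_end` per stride.
#' @param n_points Points per normalized cycle.
#' @return Data frame with `cycle` (0..1), `mean`, `sd`.
#' @export
stride_ensemble <- function(x, t, windows, n_points = 101L) {
  grid <- seq(0, 1, length.out = n_points)
  curves <- vapply(seq_len(nrow(windows)), function(i) {
    tt <- windows$t_start[i] + grid * (windows$t_end[i] - windows$t_start[i])
    stats::approx(t, x, xout = tt, rule = 2L)$y
  }, numeric(n_points))
  data.frame(cycle = grid,
             mean = rowMeans(curves),
             sd = apply(curves, 1L, stats::sd))
}

# ---------------------------------------------------------------------------
# File-backed pipeline

#' Run configuration for the pipeline
#'
#' @param params A [gait_params()].
#' @param rig A [walker_rig()].
#' @param np A [noise_params()].
#' @param enable Corrections to enable (see [measurement_schedule()]).
#' @param zupt_mode,zupt_targets,tilt_targets Scheduling options.
#' @param gyro_bias Simulated constant gyro bias magnitude, rad/s.
#' @return A list of class `run_config`.
#' @export
run_config <- function(params = gait_params(), rig = walker_rig(),
                       np = noise_params(),
                       enable = c("zupt", "tilt", "joint_center",
                                  "joint_axis"),
                       zupt_mode = "window", zupt_targets = "all_feet",
                       tilt_targets = "all",
                       gyro_bias = 10 / 3600 * pi / 180) {
  structure(list(params = params, rig = rig, np = np, enable = enable,
                 zupt_mode = zupt_mode, zupt_targets = zupt_targets,
                 tilt_targets = tilt_targets, gyro_bias = gyro_bias),
            class = "run_config")
}

.write_manifest <- function(config, dir, extra = list()) {
  man <- c(list(params = unclass(config$params),
                noise = unclass(config$np),
                rig = list(leg_length = config$rig$leg_length,
                           pelvis_width = config$rig$pelvis_width),
                enable = config$enable, zupt_mode = config$zupt_mode,
                zupt_targets = config$zupt_targets,
                tilt_targets = config$tilt_targets,
                gyro_bias = config$gyro_bias),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write a simulated walker dataset to a directory
#'
#' Writes one CSV per IMU (`t, ax, ay, az, gx, gy, gz`), the ground-truth
#' pose series (`t`, then per segment `p` and `q`), the event annotations,
#' the rig YAML and a manifest JSON recording every parameter and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the `gait_record` that was written.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- simulate_walker(config$params, config$rig, config$np,
                         gyro_bias = config$gyro_bias)
  for (nm in config$rig$imu_names) {
    df <- data.frame(t = rec$t, rec$imu[[nm]]$a, rec$imu[[nm]]$w)
    names(df) <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
    utils::write.csv(df, file.path(out_dir, paste0("imu_", nm, ".csv")),
                     row.names = FALSE)
  }
  tr <- data.frame(t = rec$t)
  for (nm in config$rig$imu_names) {
    pq <- cbind(rec$truth[[nm]]$p, rec$truth[[nm]]$q)
    colnames(pq) <- paste0(nm, "_", c("px", "py", "pz", "qw", "qx", "qy", "qz"))
    tr <- cbind(tr, pq)
  }
  utils::write.csv(tr, file.path(out_dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(rec$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  write_rig_yaml(config$rig, file.path(out_dir, "rig.yaml"))
  .write_manifest(config, out_dir, list(stage = "simulate"))
  invisible(rec)
}

#' Serialize / read a walker rig as YAML
#'
#' @param rig A [walker_rig()].
#' @param path File path.
#' @return `write_rig_yaml` returns the path invisibly; `read_rig_yaml`
#'   returns a [walker_rig()].
#' @export
write_rig_yaml <- function(rig, path) {
  obj <- list(leg_length = rig$leg_length, pelvis_width = rig$pelvis_width,
              imu_mounts = lapply(rig$imu_mounts, function(m)
                list(t = m$t, q = m$q)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_rig_yaml
#' @export
read_rig_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  walker_rig(leg_length = obj$leg_length, pelvis_width = obj$pelvis_width,
             imu_mounts = lapply(obj$imu_mounts, function(m)
               list(t = as.numeric(m$t), q = as.numeric(m$q))))
}

.read_dataset <- function(dataset_dir) {
  rig <- read_rig_yaml(file.path(dataset_dir, "rig.yaml"))
  imu <- lapply(rig$imu_names, function(nm) {
    df <- utils::read.csv(file.path(dataset_dir, paste0("imu_", nm, ".csv")))
    list(a = as.matrix(df[, c("ax", "ay", "az")]),
         w = as.matrix(df[, c("gx", "gy", "gz")]))
  })
  names(imu) <- rig$imu_names
  t <- utils::read.csv(file.path(dataset_dir,
                                 paste0("imu_", rig$imu_names[1L], ".csv")))$t
  events <- utils::read.csv(file.path(dataset_dir, "events.csv"),
                            stringsAsFactors = FALSE)
  truth <- NULL
  tp <- file.path(dataset_dir, "truth.csv")
  if (file.exists(tp)) {
    df <- utils::read.csv(tp)
    truth <- lapply(rig$imu_names, function(nm) {
      list(p = as.matrix(df[, paste0(nm, "_", c("px", "py", "pz"))]),
           q = as.matrix(df[, paste0(nm, "_", c("qw", "qx", "qy", "qz"))]))
    })
    names(truth) <- rig$imu_names
  }
  list(rig = rig, imu = structure(imu, class = "imu_signals"), t = t,
       events = events, truth = truth)
}

#' Run the filter over an on-disk dataset
#'
#' Reads a dataset written by [cmd_simulate()], runs [run_filter()] and
#' writes the state trajectory (`t`, per IMU `p`, `v`, `q`), the applied
#' measurement log (`t`, measurement rows, innovation norm) and a manifest.
#' Open-loop runs (no corrections enabled) are flagged in the manifest.
#'
#' @param dataset_dir Directory with the dataset.
#' @param out_dir Output directory.
#' @param config A [run_config()]; its scheduling options are used.
#' @return Invisibly, the `erkf_trajectory`.
#' @export
cmd_filter <- function(dataset_dir, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- .read_dataset(dataset_dir)
  sched <- measurement_schedule(ds$events, enable = config$enable,
                                zupt_mode = config$zupt_mode,
                                zupt_targets = config$zupt_targets,
                                tilt_targets = config$tilt_targets)
  traj <- run_filter(ds$imu, ds$t, ds$rig, config$np, sched)
  st <- data.frame(t = traj$t)
  for (nm in names(traj$imus)) {
    blk <- cbind(traj$imus[[nm]]$p, traj$imus[[nm]]$v, traj$imus[[nm]]$q)
    colnames(blk) <- paste0(nm, "_", c("px", "py", "pz", "vx", "vy", "vz",
                                       "qw", "qx", "qy", "qz"))
    st <- cbind(st, blk)
  }
  utils::write.csv(st, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(t = traj$t, meas_rows = traj$n_meas,
                              innovation_norm = traj$innov_norm),
                   file.path(out_dir, "measurement_log.csv"),
                   row.names = FALSE)
  .write_manifest(config, out_dir,
                  list(stage = "filter", open_loop = traj$open_loop))
  invisible(traj)
}

#' Analyze an estimate directory against its dataset
#'
#' Emits the joint-angle and spatiotemporal summary as JSON (keys
#' flexion/internal/abduction with mean/sd/rms, ROM stats, drift slopes,
#' stride and step statistics), the stride tables as CSV, and flexion
#' ensemble curves over the normalized gait cycle.
#'
#' @param estimate_dir Directory written by [cmd_filter()].
#' @param dataset_dir Directory written by [cmd_simulate()].
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly, the `gait_report`.
#' @export
cmd_analyze <- function(estimate_dir, dataset_dir, out_dir,
                        config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- .read_dataset(dataset_dir)
  if (is.null(ds$truth)) stop("cmd_analyze: dataset has no ground truth")
  st <- utils::read.csv(file.path(estimate_dir, "trajectory.csv"))
  if (max(abs(st$t - ds$t)) > 1e-9) {
    stop("cmd_analyze: estimate and dataset time bases are misaligned")
  }
  traj <- list(t = st$t, imus = lapply(ds$rig$imu_names, function(nm) {
    list(p = as.matrix(st[, paste0(nm, "_", c("px", "py", "pz"))]),
         v = as.matrix(st[, paste0(nm, "_", c("vx", "vy", "vz"))]),
         q = as.matrix(st[, paste0(nm, "_", c("qw", "qx", "qy", "qz"))]))
  }), open_loop = FALSE)
  names(traj$imus) <- ds$rig$imu_names
  class(traj) <- "erkf_trajectory"
  rec <- structure(list(t = ds$t, truth = ds$truth, events = ds$events,
                        rig = ds$rig, params = config$params),
                   class = "gait_record")
  rep <- analyze_trial(rec, traj)
  js <- list(
    angles = stats::setNames(lapply(seq_len(nrow(rep$summary)), function(i)
      list(mean = rep$summary$mean[i], sd = rep$summary$sd[i],
           rms = rep$summary$rms[i])), rep$summary$angle),
    rom_flexion = list(mean = rep$summary$rom_mean[1L],
                       sd = rep$summary$rom_sd[1L],
                       rms = rep$summary$rom_rms[1L]),
    drift_deg_per_hr = as.list(rep$drift),
    stride_length = rep$stride_stats,
    step_width = rep$step_stats
  )
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(rbind(cbind(source = "estimate", rep$strides_est),
                         cbind(source = "truth", rep$strides_true)),
                   file.path(out_dir, "strides.csv"), row.names = FALSE)
  for (s in c("left", "right")) {
    ens <- stride_ensemble(rep$angles[[s]]$est$flexion[rep$angles[[s]]$idx],
                           ds$t[rep$angles[[s]]$idx],
                           rep$angles[[s]]$windows)
    utils::write.csv(ens, file.path(out_dir,
                                    paste0("ensemble_flexion_", s, ".csv")),
                     row.names = FALSE)
  }
  invisible(rep)
}

#' Run the full simulate-filter-analyze pipeline
#'
#' @param config A [run_config()].
#' @param out_dir Root output directory; `dataset/`, `estimate/` and
#'   `report/` subdirectories are created.
#' @return The `gait_report`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dd <- file.path(out_dir, "dataset")
  ed <- file.path(out_dir, "estimate")
  rd <- file.path(out_dir, "report")
  cmd_simulate(config, dd)
  cmd_filter(dd, ed, config)
  invisible(cmd_analyze(ed, dd, rd, config))
}
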