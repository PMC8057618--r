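# Event detection, hip joint angles, spatiotemporal gait metrics and
# comparison statistics.

#' Detect still periods from IMU signals
#'
#' Maximal windows where the gyroscope magnitude stays below `w_thresh` and
#' the accelerometer magnitude stays within `a_thresh` of gravity for at
#' least `min_duration`. Intended for clean or lightly filtered signals;
#' pipelines with annotated events (as simulation provides) can bypass
#' detection entirely by passing those annotations downstream.
#'
#' @param w Gyroscope series, n x 3, rad/s.
#' @param a Accelerometer series, n x 3, m/s^2.
#' @param t Sample times, s.
#' @param w_thresh Angular-rate threshold, rad/s (default 2 deg/s).
#' @param a_thresh Acceleration-magnitude threshold, m/s^2.
#' @param min_duration Minimum window length, s.
#' @param gravity Gravity magnitude, m/s^2.
#' @return Data frame with `t_start`, `t_end`.
#' @export
detect_still_periods <- function(w, a, t, w_thresh = 2 * pi / 180,
                                 a_thresh = 0.5, min_duration = 0.05,
                                 gravity = 9.81) {
  wn <- sqrt(rowSums(w^2))
  an <- sqrt(rowSums(a^2))
  still <- wn < w_thresh & abs(an - gravity) < a_thresh
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(t_start = t[starts[keep]], t_end = t[ends[keep]])
  out[out$t_end - out$t_start >= min_duration - 1e-9, , drop = FALSE]
}

#' Footfall instants from still windows
#'
#' One instant per window, at the window midpoint.
#'
#' @param windows Data frame with `t_start`, `t_end`.
#' @return Numeric vector of footfall times, ordered.
#' @export
detect_footfalls <- function(windows) {
  if (nrow(windows) == 0L) return(numeric(0L))
  sort((windows$t_start + windows$t_end) / 2)
}

# Unwrap an angle series (degrees) to remove 360-degree jumps.
.unwrap_deg <- function(x) {
  d <- diff(x)
  corr <- cumsum(round(d / 360)) * -360
  x + c(0, corr)
}

#' Hip joint angles from pelvis and leg orientations
#'
#' Decomposes the relative pelvis-to-leg rotation by the mobile Z-X-Y
#' sequence of the ISB hip convention: flexion(+)/extension about the pelvis
#' z-axis (the hinge axis, pointing right), ab(+)/adduction about the
#' floating x-axis, internal(+)/external rotation about the leg y-axis. For
#' the left side the ab/adduction and internal/external signs are mirrored
#' so positive values are medially directed on both sides. Angles are
#' returned in degrees, unwrapped over time.
#'
#' @param q_pelvis n x 4 pelvis orientation quaternions (body to world).
#' @param q_leg n x 4 leg orientation quaternions.
#' @param side `"right"` or `"left"`.
#' @return Data frame with `flexion`, `adduction`, `internal` (degrees) and
#'   a `gimbal` flag marking samples within 1 degree of the +/-90 degree
#'   ab/adduction singularity.
#' @export
hip_angles <- function(q_pelvis, q_leg, side = c("right", "left")) {
  side <- match.arg(side)
  if (is.null(dim(q_pelvis))) q_pelvis <- matrix(q_pelvis, 1L, 4L)
  if (is.null(dim(q_leg))) q_leg <- matrix(q_leg, 1L, 4L)
  qp_conj <- cbind(q_pelvis[, 1L], -q_pelvis[, 2L], -q_pelvis[, 3L],
                   -q_pelvis[, 4L])
  qr <- .qmult_rows(qp_conj, q_leg)
  w <- qr[, 1L]; x <- qr[, 2L]; y <- qr[, 3L]; z <- qr[, 4L]
  nrm <- sqrt(w^2 + x^2 + y^2 + z^2)
  w <- w / nrm; x <- x / nrm; y <- y / nrm; z <- z / nrm
  m32 <- 2 * (y * z + w * x)
  m12 <- 2 * (x * y - w * z)
  m22 <- 1 - 2 * (x^2 + z^2)
  m31 <- 2 * (x * z - w * y)
  m33 <- 1 - 2 * (x^2 + y^2)
  flex <- atan2(-m12, m22) * 180 / pi
  add <- asin(pmin(pmax(m32, -1), 1)) * 180 / pi
  int <- atan2(-m31, m33) * 180 / pi
  if (side == "left") {
    add <- -add
    int <- -int
  }
  data.frame(flexion = .unwrap_deg(flex),
             adduction = add,
             internal = .unwrap_deg(int),
             gimbal = abs(abs(add) - 90) < 1)
}

# Horizontal unit travel direction from a position series (principal
# direction of horizontal displacement, sign-aligned with net displacement).
.travel_direction <- function(pos, up = c(0, 0, 1)) {
  up <- up / sqrt(sum(up^2))
  horiz <- pos - outer(as.numeric(pos %*% up), up)
  ctr <- sweep(horiz, 2L, colMeans(horiz))
  pc <- eigen(crossprod(ctr), symmetric = TRUE)$vectors[, 1L]
  pc <- pc - sum(pc * up) * up
  pc <- pc / sqrt(sum(pc^2))
  net <- horiz[nrow(horiz), ] - horiz[1L, ]
  if (sum(net * pc) < 0) pc <- -pc
  pc
}

# Linear interpolation of an n x 3 position series at arbitrary times.
.interp_pos <- function(t, pos, t_out) {
  vapply(1:3, function(c1) stats::approx(t, pos[, c1], xout = t_out,
                                         rule = 2L)$y,
         numeric(length(t_out)))
}

#' Stride length and step width from foot trajectories
#'
#' Stride length is the horizontal displacement of one foot's IMU between
#' its consecutive footfalls; step width is the lateral
#' (perpendicular-to-travel) separation of the two feet's IMU positions at
#' successive alternating footfalls. A stride is flagged straight when its
#' displacement lies within `max_angle` of the primary travel direction and
#' its length exceeds `min_length`; the first (transition) stride of each
#' foot, and steps touching it, are excluded when `exclude_transition`.
#'
#' @param t Sample times, s.
#' @param pos_left,pos_right Foot-IMU position series, n x 3, m.
#' @param ff_left,ff_right Footfall times per foot, s.
#' @param sacrum Optional sacrum position series used for the travel
#'   direction; defaults to the pooled foot positions.
#' @param up World up unit vector.
#' @param max_angle Straight-stride angular tolerance, degrees.
#' @param min_length Straight-stride minimum length, m.
#' @param exclude_transition Drop each foot's first stride and the steps
#'   that touch it.
#' @return A list with data.frames `strides` (side, t_start, t_end,
#'   stride_length, straight), `steps` (t, width) and the unit `travel_dir`.
#' @export
stride_metrics <- function(t, pos_left, pos_right, ff_left, ff_right,
                           sacrum = NULL, up = c(0, 0, 1), max_angle = 15,
                           min_length = 0.2, exclude_transition = TRUE) {
  if (length(ff_left) < 2L && length(ff_right) < 2L) {
    stop("stride_metrics: need at least two footfalls for one foot")
  }
  up <- up / sqrt(sum(up^2))
  ref <- if (!is.null(sacrum)) sacrum else rbind(pos_left, pos_right)
  dir <- .travel_direction(ref, up)
  lat <- c(up[2L] * dir[3L] - up[3L] * dir[2L],
           up[3L] * dir[1L] - up[1L] * dir[3L],
           up[1L] * dir[2L] - up[2L] * dir[1L])

  one_side <- function(ff, pos, side) {
    if (length(ff) < 2L) {
      return(data.frame(side = character(), t_start = numeric(),
                        t_end = numeric(), stride_length = numeric(),
                        straight = logical()))
    }
    pts <- .interp_pos(t, pos, ff)
    disp <- diff(pts)
    horiz <- disp - outer(as.numeric(disp %*% up), up)
    len <- sqrt(rowSums(horiz^2))
    ang <- acos(pmin(pmax(as.numeric(horiz %*% dir) / pmax(len, 1e-12), -1), 1)) *
      180 / pi
    data.frame(side = side, t_start = ff[-length(ff)], t_end = ff[-1L],
               stride_length = len,
               straight = ang <= max_angle & len > min_length,
               stringsAsFactors = FALSE)
  }
  strides <- rbind(one_side(ff_left, pos_left, "left"),
                   one_side(ff_right, pos_right, "right"))
  strides <- strides[order(strides$t_start), , drop = FALSE]

  # alternating footfalls, both feet pooled. Step width is measured
  # perpendicular to a time-local travel direction -- the sacrum
  # displacement over the step's own footfall interval when a sacrum series
  # is supplied, else the leading foot's stride displacement -- so that
  # slow, unobservable global-heading wander does not leak the forward step
  # component into the lateral separation; the trial-wide direction is the
  # fallback.
  ff_all <- rbind(data.frame(t = ff_left, foot = "left"),
                  data.frame(t = ff_right, foot = "right"))
  ff_all <- ff_all[order(ff_all$t), , drop = FALSE]
  steps <- data.frame(t = numeric(), width = numeric(), foot = character())
  if (nrow(ff_all) >= 2L) {
    alt <- ff_all$foot[-1L] != ff_all$foot[-nrow(ff_all)]
    i2 <- which(alt) + 1L
    getpos <- function(times, feet) {
      pl <- .interp_pos(t, pos_left, times)
      pr <- .interp_pos(t, pos_right, times)
      ifelse(matrix(feet == "left", length(times), 3L), pl, pr)
    }
    pa <- getpos(ff_all$t[i2 - 1L], ff_all$foot[i2 - 1L])
    pb <- getpos(ff_all$t[i2], ff_all$foot[i2])
    stride_dir <- function(foot_b, t_b) {
      ffb <- if (foot_b == "left") ff_left else ff_right
      posb <- if (foot_b == "left") pos_left else pos_right
      j <- which(abs(ffb - t_b) < 1e-9)
      if (length(j) != 1L || j < 2L) return(dir)
      d <- .interp_pos(t, posb, ffb[c(j - 1L, j)])
      dd <- d[2L, ] - d[1L, ]
      dd <- dd - sum(dd * up) * up
      nd <- sqrt(sum(dd^2))
      if (nd < 1e-9) dir else dd / nd
    }
    local_dir <- function(s) {
      tA <- ff_all$t[i2[s] - 1L]; tB <- ff_all$t[i2[s]]
      if (!is.null(sacrum)) {
        d <- .interp_pos(t, sacrum, c(tA, tB))
        dd <- d[2L, ] - d[1L, ]
        dd <- dd - sum(dd * up) * up
        nd <- sqrt(sum(dd^2))
        if (nd >= 1e-9) return(dd / nd)
      }
      stride_dir(ff_all$foot[i2[s]], tB)
    }
    width <- vapply(seq_along(i2), function(s) {
      dl <- local_dir(s)
      latl <- c(up[2L] * dl[3L] - up[3L] * dl[2L],
                up[3L] * dl[1L] - up[1L] * dl[3L],
                up[1L] * dl[2L] - up[2L] * dl[1L])
      abs(sum((pb[s, ] - pa[s, ]) * latl))
    }, numeric(1L))
    steps <- data.frame(t = ff_all$t[i2], width = width,
                        foot = ff_all$foot[i2], stringsAsFactors = FALSE)
  }

  if (exclude_transition) {
    first_end <- c(left = if (length(ff_left) >= 2L) ff_left[2L] else -Inf,
                   right = if (length(ff_right) >= 2L) ff_right[2L] else -Inf)
    # a stride is the transition stride iff it is the first of its side
    is_first <- !duplicated(strides$side)
    strides <- strides[!is_first, , drop = FALSE]
    drop_before <- suppressWarnings(min(first_end[is.finite(first_end)]))
    steps <- steps[steps$t > drop_before + 1e-9, , drop = FALSE]
  }
  list(strides = strides, steps = steps, travel_dir = dir)
}

#' Compare an estimated series against a reference
#'
#' Per-sample differences (estimate minus reference) summarized by mean, SD
#' and RMS, plus the least-squares drift slope of the difference versus time
#' (reported in units/hr) and, when stride windows are supplied, per-stride
#' range-of-motion differences.
#'
#' @param est,ref Aligned numeric series.
#' @param t Sample times, s (needed for the drift slope).
#' @param stride_windows Optional data.frame with `t_start`, `t_end`; ROM
#'   (max minus min) is computed per window for both series.
#' @return A list of class `comparison_stats`: `mean_diff`, `sd_diff`,
#'   `rms_diff`, `drift_slope` (units/hr), `n`, and optionally `rom`
#'   (per-stride data.frame) with `rom_mean_diff`, `rom_sd_diff`,
#'   `rom_rms_diff`.
#' @export
compare_series <- function(est, ref, t = NULL, stride_windows = NULL) {
  if (length(est) != length(ref)) {
    stop("compare_series: series lengths differ (", length(est), " vs ",
         length(ref), ")")
  }
  d <- est - ref
  n <- length(d)
  out <- list(mean_diff = mean(d),
              sd_diff = stats::sd(d),
              rms_diff = sqrt(mean(d^2)),
              n = n)
  out$drift_slope <- if (!is.null(t) && n >= 2L) {
    unname(stats::coef(stats::lm.fit(cbind(1, t), d))[2L]) * 3600
  } else NA_real_
  if (!is.null(stride_windows) && nrow(stride_windows) > 0L && !is.null(t)) {
    rom <- vapply(seq_len(nrow(stride_windows)), function(i) {
      idx <- t >= stride_windows$t_start[i] - 1e-9 &
        t <= stride_windows$t_end[i] + 1e-9
      if (!any(idx)) return(c(est = NA_real_, ref = NA_real_))
      c(est = diff(range(est[idx])), ref = diff(range(ref[idx])))
    }, numeric(2L))
    romd <- rom["est", ] - rom["ref", ]
    out$rom <- data.frame(t_start = stride_windows$t_start,
                          rom_est = rom["est", ], rom_ref = rom["ref", ])
    out$rom_mean_diff <- mean(romd, na.rm = TRUE)
    out$rom_sd_diff <- stats::sd(romd, na.rm = TRUE)
    out$rom_rms_diff <- sqrt(mean(romd^2, na.rm = TRUE))
  }
  structure(out, class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.4g, RMS %.4g (n = %d)",
              x$mean_diff, x$sd_diff, x$rms_diff, x$n))
  if (!is.na(x$drift_slope)) cat(sprintf(", drift %.4g /hr", x$drift_slope))
  cat("\n")
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Mean difference (estimate minus reference) and the 95% limits of
#' agreement, mean +/- 1.96 SD.
#'
#' @param est,ref Paired numeric vectors (n >= 2).
#' @return A list with `mean_diff`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  if (length(est) < 2L) stop("bland_altman: need at least 2 paired samples")
  d <- est - ref
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       sd_diff = s, n = length(d))
}
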