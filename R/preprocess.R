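## IMU preprocessing: zero-phase Butterworth filtering, magnetometer-free
## orientation fusion, gravity removal, frame transformation and trapezoid
## integration to velocity.

.axis_mat <- function(df, cols) {
  m <- as.matrix(as.data.frame(df)[cols])
  dimnames(m) <- NULL
  m
}

#' Zero-phase filtering with odd-reflection padding
#'
#' Forward-backward application of an IIR filter.  The series is extended at
#' both ends by odd reflection over `pad` samples, and each pass starts from
#' the filter's steady state for the first padded sample, so edge transients
#' stay bounded and deterministic.
#' @noRd
.filtfilt_pad <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    head_ext <- 2 * x[1L] - x[(pad + 1L):2L]
    tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
    ext <- c(head_ext, x, tail_ext)
  } else ext <- x
  g <- sum(b) / sum(a) # DC gain
  run <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1L], length(b) - 1L),
                              init.y = rep(g * z[1L], length(a) - 1L)))
  }
  y <- rev(run(rev(run(ext))))
  if (pad > 0L) y[(pad + 1L):(pad + n)] else y
}

.butter_apply <- function(x, fs, fc, order, type) {
  w <- fc / (fs / 2)
  bf <- signal::butter(order, w, type = type)
  m <- as.matrix(x)
  # short odd-reflection pad; start-up transients are handled by the
  # steady-state initial conditions, the pad only guards the filter warm-up
  pad <- min(nrow(m) - 1L, 6L * (length(bf$a) - 1L))
  apply(m, 2L, function(col) .filtfilt_pad(bf$b, bf$a, col, pad))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters each channel of a multi-channel series with a Butterworth low-pass
#' applied forward and backward (zero phase), preserving the timing of zero
#' crossings.
#'
#' @param x Data frame or matrix of channels (one column per channel), or a
#'   numeric vector.
#' @param fs Sample rate (Hz).
#' @param fc Cut-off frequency (Hz), must be below the Nyquist rate.
#' @param order Filter order (default 6).
#' @return Filtered series with the shape and column names of `x`.
#' @export
lowpass_filter <- function(x, fs, fc = 10, order = 6) {
  if (fc >= fs / 2) stop("`fc` must be below the Nyquist frequency fs/2")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  if (nrow(m) <= 3L * order) stop("series too short for the requested order")
  out <- .butter_apply(m, fs, fc, order, "low")
  if (vec) return(as.numeric(out))
  if (is.data.frame(x)) {
    res <- tibble::as_tibble(as.data.frame(out))
    names(res) <- colnames(x)
    res
  } else out
}

#' Low-pass filter the six motion channels of an IMU recording
#'
#' Applies [lowpass_filter()] to the acceleration and gyroscope channels,
#' leaving `t` untouched.
#'
#' @inheritParams lowpass_filter
#' @param rec An [imu_recording()].
#' @return A filtered `imu_recording`.
#' @export
filter_imu <- function(rec, fc = 10, order = 6) {
  fs <- imu_fs(rec)
  ch <- c("ax", "ay", "az", "gx", "gy", "gz")
  filt <- lowpass_filter(tibble::as_tibble(rec)[ch], fs, fc = fc, order = order)
  out <- tibble::as_tibble(rec)
  out[ch] <- filt
  imu_recording(out, site = imu_site(rec), fs = fs)
}

#' Estimate sensor orientation from accelerometer and gyroscope
#'
#' Gradient-descent (Madgwick-style) fusion without a magnetometer: the
#' gyroscope is integrated and continuously corrected toward the
#' accelerometer's gravity direction.  The global frame has its z-axis
#' aligned with gravity; heading is unobservable and held by gyroscope
#' integration alone.  The initial attitude is taken from the mean
#' accelerometer vector over the first second (tilt only, zero yaw).
#'
#' @param rec An [imu_recording()] (ideally already low-pass filtered).
#' @param beta Fusion gain (rad/s); larger values trust the accelerometer
#'   more. Default 0.1.
#' @param init_window_s Length of the startup window used for the initial
#'   attitude (s).
#' @return An n x 4 matrix of unit quaternions (scalar first) mapping the
#'   sensor's local frame to the global frame, of class `orientation_track`.
#' @export
estimate_orientation <- function(rec, beta = 0.1, init_window_s = 1) {
  fs <- imu_fs(rec)
  acc <- .axis_mat(rec, c("ax", "ay", "az"))
  gyr <- .axis_mat(rec, c("gx", "gy", "gz"))
  n <- nrow(acc)
  if (all(abs(acc) < 1e-12)) stop("degenerate input: accelerometer stream is all zero")
  i0 <- max(2L, min(n, round(init_window_s * fs)))
  a0 <- colMeans(acc[seq_len(i0), , drop = FALSE])
  if (sqrt(sum(a0^2)) < 1e-9) stop("degenerate input: no gravity signal in startup window")
  q <- quat_between(a0 / sqrt(sum(a0^2)), c(0, 0, 1))
  dt <- 1 / fs
  out <- matrix(0, n, 4L)
  q0 <- q[1L]; q1 <- q[2L]; q2 <- q[3L]; q3 <- q[4L]
  for (i in seq_len(n)) {
    wx <- gyr[i, 1L]; wy <- gyr[i, 2L]; wz <- gyr[i, 3L]
    # rate of change from gyroscope: 0.5 * q x (0, omega)
    dq0 <- 0.5 * (-q1 * wx - q2 * wy - q3 * wz)
    dq1 <- 0.5 * (q0 * wx + q2 * wz - q3 * wy)
    dq2 <- 0.5 * (q0 * wy - q1 * wz + q3 * wx)
    dq3 <- 0.5 * (q0 * wz + q1 * wy - q2 * wx)
    an <- sqrt(acc[i, 1L]^2 + acc[i, 2L]^2 + acc[i, 3L]^2)
    if (an > 1e-9) {
      axh <- acc[i, 1L] / an; ayh <- acc[i, 2L] / an; azh <- acc[i, 3L] / an
      # objective: predicted gravity direction in the local frame minus the
      # measured one; gradient via the Jacobian of R(q)^T z-hat
      f1 <- 2 * (q1 * q3 - q0 * q2) - axh
      f2 <- 2 * (q2 * q3 + q0 * q1) - ayh
      f3 <- 1 - 2 * (q1 * q1 + q2 * q2) - azh
      g0 <- -2 * q2 * f1 + 2 * q1 * f2
      g1 <- 2 * q3 * f1 + 2 * q0 * f2 - 4 * q1 * f3
      g2 <- -2 * q0 * f1 + 2 * q3 * f2 - 4 * q2 * f3
      g3 <- 2 * q1 * f1 + 2 * q2 * f2
      gn <- sqrt(g0 * g0 + g1 * g1 + g2 * g2 + g3 * g3)
      if (gn > 1e-12) {
        dq0 <- dq0 - beta * g0 / gn
        dq1 <- dq1 - beta * g1 / gn
        dq2 <- dq2 - beta * g2 / gn
        dq3 <- dq3 - beta * g3 / gn
      }
    }
    q0 <- q0 + dq0 * dt; q1 <- q1 + dq1 * dt
    q2 <- q2 + dq2 * dt; q3 <- q3 + dq3 * dt
    qn <- sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3)
    q0 <- q0 / qn; q1 <- q1 / qn; q2 <- q2 / qn; q3 <- q3 / qn
    out[i, 1L] <- q0; out[i, 2L] <- q1; out[i, 3L] <- q2; out[i, 4L] <- q3
  }
  structure(out, class = c("orientation_track", "matrix", "array"))
}

.check_len <- function(a, b, what) {
  if (nrow(as.matrix(a)) != nrow(.as_qmat(b))) {
    stop("length mismatch between ", what)
  }
}

#' Gravity-free acceleration in the global frame
#'
#' Rotates local-frame acceleration into the gravity-aligned global frame
#' using the orientation track, then removes each axis' mean so the static
#' gravity component (and any residual bias) vanishes.
#'
#' @param rec An [imu_recording()] (filtered).
#' @param q An `orientation_track` for the same recording.
#' @return A tibble `t, ax, ay, az` with attribute `frame = "global"`; each
#'   axis has zero mean.
#' @export
to_global_linear_accel <- function(rec, q) {
  acc <- .axis_mat(rec, c("ax", "ay", "az"))
  .check_len(acc, q, "recording and orientation track")
  ag <- quat_rotate(q, acc)
  ag <- sweep(ag, 2L, colMeans(ag))
  out <- tibble::tibble(t = rec$t, ax = ag[, 1L], ay = ag[, 2L], az = ag[, 3L])
  attr(out, "frame") <- "global"
  out
}

#' Rotate global-frame acceleration into the body (trunk) frame
#'
#' Applies the inverse of the sternum sensor's orientation per sample, so the
#' axes align with the subject's anatomical axes.  Rotation preserves the
#' per-sample norm.
#'
#' @param awg Tibble `t, ax, ay, az` in the global frame.
#' @param q_sternum Sternum `orientation_track` of the same length.
#' @return A tibble with attribute `frame = "body"`.
#' @export
to_body_frame <- function(awg, q_sternum) {
  a <- .axis_mat(awg, c("ax", "ay", "az"))
  .check_len(a, q_sternum, "acceleration and sternum orientation")
  ab <- quat_rotate(quat_conjugate(q_sternum), a)
  out <- tibble::tibble(t = awg$t, ax = ab[, 1L], ay = ab[, 2L], az = ab[, 3L])
  attr(out, "frame") <- "body"
  out
}

#' Integrate acceleration to velocity with drift suppression
#'
#' Per-axis cumulative trapezoid integration followed by a zero-phase
#' 2nd-order Butterworth band-pass (0.1-10 Hz by default) that removes the
#' low-frequency integration drift and residual high-frequency noise.
#'
#' @param a Tibble `t, ax, ay, az` (m/s^2).
#' @param fs Sample rate (Hz).
#' @param band Band-pass cut-offs (Hz).
#' @param order Band-pass order (default 2).
#' @return A tibble `t, vx, vy, vz` (m/s) carrying the input's `frame`
#'   attribute.
#' @export
integrate_velocity <- function(a, fs, band = c(0.1, 10), order = 2) {
  m <- .axis_mat(a, c("ax", "ay", "az"))
  if (!all(is.finite(m))) stop("acceleration must be finite")
  v <- .cumtrapz_fs(m, fs)
  v <- .butter_apply(v, fs, band, order, "pass")
  out <- tibble::tibble(t = a$t, vx = v[, 1L], vy = v[, 2L], vz = v[, 3L])
  attr(out, "frame") <- attr(a, "frame")
  out
}

#' Wrist velocity in the global or body frame
#'
#' Convenience chains running the full preprocessing pipeline:
#' low-pass filtering (10 Hz, order 6) of both motion channels, orientation
#' fusion, gravity removal, optional rotation into the trunk frame (with a
#' second low-pass of the body-frame acceleration), then trapezoid
#' integration with 0.1-10 Hz band-pass drift suppression.
#'
#' @param wrist Wrist [imu_recording()].
#' @param sternum Sternum [imu_recording()] (body frame only).
#' @param q_wrist,q_sternum Optional precomputed orientation tracks (e.g.
#'   ground truth from the simulator); estimated when `NULL`.
#' @param fc,order Low-pass settings.
#' @param second_lowpass Re-apply the low-pass to the body-frame acceleration
#'   before integration (default `TRUE`).
#' @return A tibble `t, vx, vy, vz` with attribute `frame`.
#' @export
body_velocity <- function(wrist, sternum, q_wrist = NULL, q_sternum = NULL,
                          fc = 10, order = 6, second_lowpass = TRUE) {
  fs <- imu_fs(wrist)
  wf <- filter_imu(wrist, fc = fc, order = order)
  sf <- filter_imu(sternum, fc = fc, order = order)
  if (is.null(q_wrist)) q_wrist <- estimate_orientation(wf)
  if (is.null(q_sternum)) q_sternum <- estimate_orientation(sf)
  awg <- to_global_linear_accel(wf, q_wrist)
  awb <- to_body_frame(awg, q_sternum)
  if (second_lowpass) {
    ch <- c("ax", "ay", "az")
    awb[ch] <- lowpass_filter(awb[ch], fs, fc = fc, order = order)
  }
  integrate_velocity(awb, fs)
}

#' @rdname body_velocity
#' @export
global_velocity <- function(wrist, q_wrist = NULL, fc = 10, order = 6) {
  fs <- imu_fs(wrist)
  wf <- filter_imu(wrist, fc = fc, order = order)
  if (is.null(q_wrist)) q_wrist <- estimate_orientation(wf)
  awg <- to_global_linear_accel(wf, q_wrist)
  integrate_velocity(awg, fs)
}
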