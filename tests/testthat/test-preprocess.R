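test_that("zero-phase Butterworth low-pass has the analytic response", {
  fs <- 50
  t <- seq(0, 20, by = 1 / fs)
  # DC gain 1
  const <- rep(2.5, length(t))
  expect_lt(max(abs(lowpass_filter(const, fs) - 2.5)), 1e-9)
  # 20 Hz sine: the bilinear-transformed order-6 Butterworth with prewarped
  # cut-off has single-pass magnitude 1/sqrt(1 + (tan(w/2)/tan(wc/2))^12);
  # zero-phase application squares the magnitude response
  x20 <- sin(2 * pi * 20 * t)
  y20 <- lowpass_filter(x20, fs)
  mid <- 300:700
  warp <- tan(pi * 20 / fs) / tan(pi * 10 / fs)
  gain_digital <- 1 / sqrt(1 + warp^12)
  expect_equal(max(abs(y20[mid])), gain_digital^2, tolerance = 0.2)
  # and at least the attenuation the analog prototype promises (~ -36 dB,
  # doubled by the forward-backward pass)
  gain_analog <- 1 / sqrt(1 + (20 / 10)^12)
  expect_lt(max(abs(y20[mid])), gain_analog^2)
  # 1 Hz sine preserved within 2%
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(x1, fs)
  expect_equal(max(abs(y1[mid])), 1, tolerance = 0.02)
  expect_error(lowpass_filter(x1, fs, fc = 25), "Nyquist")
})

test_that("orientation fusion finds gravity and tracks yaw rate", {
  fs <- 50
  n <- 5 * fs
  static <- imu_recording(tibble::tibble(
    t = (seq_len(n) - 1) / fs, ax = 0, ay = 0, az = 9.81,
    gx = 0, gy = 0, gz = 0), site = "wrist", fs = fs)
  q <- estimate_orientation(static)
  g_err <- segmotor:::quat_tilt_error(q, matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE))
  expect_lt(max(g_err[(2 * fs):n]) * 180 / pi, 1)
  # constant yaw rate: yaw change ~ omega * T (oracle: direct quaternion
  # integration of the same gyro stream)
  omega <- 0.5; T <- 6
  n2 <- T * fs
  spin <- imu_recording(tibble::tibble(
    t = (seq_len(n2) - 1) / fs, ax = 0, ay = 0, az = 9.81,
    gx = 0, gy = 0, gz = omega), site = "wrist", fs = fs)
  qe <- estimate_orientation(spin)
  yaw <- function(qrow) atan2(2 * (qrow[1] * qrow[4] + qrow[2] * qrow[3]),
                              1 - 2 * (qrow[3]^2 + qrow[4]^2))
  q_oracle <- segmotor:::quat_integrate(cbind(0, 0, rep(omega, n2)), fs)
  expect_equal(yaw(qe[n2, ]), yaw(q_oracle[n2, ]), tolerance = 0.02 * abs(yaw(q_oracle[n2, ])))
  expect_equal(yaw(qe[n2, ]), omega * (n2 - 1) / fs, tolerance = 0.02 * omega * T)
  # unit norm throughout
  expect_lt(max(abs(sqrt(rowSums(qe^2)) - 1)), 1e-9)
  zero <- imu_recording(tibble::tibble(t = (seq_len(n) - 1) / fs, ax = 0, ay = 0,
                                       az = 0, gx = 0, gy = 0, gz = 0),
                        site = "wrist", fs = fs)
  expect_error(estimate_orientation(zero), "degenerate")
})

test_that("orientation estimate stays within 3 degrees of simulator truth", {
  rec <- simulate_subject(subject_spec("S", 0.4, duration_s = 60, seed = 21))
  q <- estimate_orientation(filter_imu(rec$wrist))
  tilt <- segmotor:::quat_tilt_error(q, rec$truth$q_wrist)
  expect_lt(mean(tilt) * 180 / pi, 3)
})

test_that("gravity removal leaves zero-mean global acceleration", {
  fs <- 50; n <- 4 * fs
  static <- imu_recording(tibble::tibble(
    t = (seq_len(n) - 1) / fs, ax = 0, ay = 0, az = 9.81,
    gx = 0, gy = 0, gz = 0), site = "wrist", fs = fs)
  q <- estimate_orientation(static)
  ag <- to_global_linear_accel(static, q)
  expect_lt(max(abs(as.matrix(ag[c("ax", "ay", "az")]))), 1e-3)
  expect_lt(max(abs(colMeans(as.matrix(ag[c("ax", "ay", "az")])))), 1e-9)
  expect_error(to_global_linear_accel(static, q[1:10, ]), "length mismatch")
  # known trajectory with truth orientation: recovered acceleration tracks
  # the trajectory's second derivative
  rec <- simulate_subject(subject_spec("S", 0.2, duration_s = 30, seed = 3),
                          accel_noise_sd = 0, gyro_noise_sd = 0)
  ag2 <- to_global_linear_accel(rec$wrist, rec$truth$q_wrist)
  for (k in 1:3) {
    expect_gt(cor(ag2[[k + 1]], rec$truth$a_global[, k]), 0.99)
  }
})

test_that("body-frame rotation matches hand-computed cases and preserves norms", {
  awg <- tibble::tibble(t = c(0, 0.02, 0.04), ax = c(1, 2, 3), ay = c(0, -1, 0.5),
                        az = c(0.2, 0, -0.3))
  n <- nrow(awg)
  q_id <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  expect_equal(to_body_frame(awg, q_id)[c("ax", "ay", "az")],
               awg[c("ax", "ay", "az")], ignore_attr = TRUE)
  # 90 degree torso yaw: global y becomes body x
  q_yaw <- matrix(rep(c(cos(pi / 4), 0, 0, sin(pi / 4)), n), n, 4, byrow = TRUE)
  ab <- to_body_frame(awg, q_yaw)
  expect_equal(ab$ax, awg$ay, tolerance = 1e-12)
  expect_equal(ab$ay, -awg$ax, tolerance = 1e-12)
  expect_equal(ab$az, awg$az, tolerance = 1e-12)
  norms_in <- sqrt(rowSums(as.matrix(awg[c("ax", "ay", "az")])^2))
  norms_out <- sqrt(rowSums(as.matrix(ab[c("ax", "ay", "az")])^2))
  expect_lt(max(abs(norms_in - norms_out)), 1e-9)
  expect_error(to_body_frame(awg, q_id[1:2, ]), "length mismatch")
})

test_that("trapezoid integration with band-pass recovers pulses, rejects drift", {
  fs <- 50
  fx <- reach_recording(amplitude = 0.3, duration = 1, axis = 1, fs = fs)
  a <- tibble::tibble(t = fx$t, ax = fx$wrist$ax, ay = fx$wrist$ay,
                      az = fx$wrist$az - 9.81)
  v <- integrate_velocity(a, fs)
  # compare over the movement and its immediate surroundings (the 0.1 Hz
  # drift filter leaves a small, slowly decaying undershoot far from it)
  win <- fx$t >= fx$pulse_window[1] - 1 & fx$t <= fx$pulse_window[2] + 1
  expect_gt(cor(v$vx[win], fx$v[win, 1]), 0.99)
  expect_gt(cor(v$vx, fx$v[, 1]), 0.97)
  # zero in, zero out
  z <- integrate_velocity(tibble::tibble(t = fx$t, ax = 0, ay = 0, az = 0), fs)
  expect_lt(max(abs(z$vx)), 1e-12)
  # a constant bias integrates to a ramp; the 0.1 Hz high-pass removes it
  b <- integrate_velocity(tibble::tibble(t = fx$t, ax = 0.05, ay = 0, az = 0), fs)
  ramp_end <- 0.05 * max(fx$t)
  expect_lt(abs(mean(b$vx)), 0.02 * ramp_end)
})

test_that("preprocessing chain is deterministic and frame-faithful", {
  rec <- simulate_subject(subject_spec("S", 0.3, duration_s = 45, seed = 12),
                          accel_noise_sd = 0, gyro_noise_sd = 0)
  v1 <- body_velocity(rec$wrist, rec$sternum)
  v2 <- body_velocity(rec$wrist, rec$sternum)
  expect_identical(v1, v2)
  # with truth orientation the body-frame velocity tracks the rotated truth
  vb <- body_velocity(rec$wrist, rec$sternum,
                      q_wrist = rec$truth$q_wrist, q_sternum = rec$truth$q_sternum)
  vt <- segmotor:::quat_rotate(segmotor:::quat_conjugate(rec$truth$q_sternum),
                               rec$truth$v_global)
  for (k in 1:3) expect_gt(cor(vb[[k + 1]], vt[, k]), 0.98)
})
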