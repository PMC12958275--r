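test_that("zero-crossing decomposition equals a brute-force sign-run scan", {
  fs <- 50
  # sine over exactly 3 periods: 6 alternating-sign segments
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  v <- sin(2 * pi * t)
  segs <- segment_zero_crossings(v, fs)
  expect_equal(nrow(segs), 6L)
  expect_equal(segs$sign, rep(c(1L, -1L), 3))
  # all-non-negative series: one segment on the active region
  v2 <- c(rep(0, 10), rep(0.2, 30), rep(0, 10))
  expect_equal(nrow(segment_zero_crossings(v2, fs)), 1L)
  # random signals vs the oracle
  set.seed(11)
  for (i in 1:25) {
    v3 <- cumsum(rnorm(200)) / 10
    segs3 <- segment_zero_crossings(v3, fs)
    orc <- oracle_sign_runs(v3)
    expect_equal(nrow(segs3), nrow(orc))
    expect_equal(segs3$start_idx, orc$start)
    expect_equal(segs3$end_idx, orc$end + 1L)
    expect_equal(segs3$sign, orc$sign)
    # sign-constancy and tiling of the non-zero support
    expect_true(all(vapply(segs3$profile, function(p) all(p > 0) || all(p < 0), TRUE)))
    covered <- unlist(purrr::map2(segs3$start_idx, segs3$end_idx - 1L, seq))
    expect_equal(sort(covered), which(abs(v3) >= 1e-4))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("quality filters apply their boundaries exactly", {
  segs <- tibble::tibble(
    axis = "x", start_idx = 1L, end_idx = 2L,
    duration = c(0.050, 0.060, 0.060, 0.051),
    displacement = c(0.005, 0.0005, 0.0010, 0.002),
    sign = 1L, profile = list(1, 1, 1, 1))
  kept <- filter_segments(segs)
  # duration of exactly 50 ms is removed; sub-millimetre travel is removed;
  # the 1 mm displacement boundary itself is retained
  expect_equal(kept$duration, c(0.060, 0.051))
  expect_equal(kept$displacement, c(0.0010, 0.002))
})

test_that("a pure body-x reach yields exactly one substantive x segment", {
  fx <- reach_recording(amplitude = 0.3, duration = 1, axis = 1)
  segs <- anatomical_segments(fx$wrist, fx$sternum,
                              q_wrist = fx$q_identity, q_sternum = fx$q_identity)
  # the DC-blocking drift filter flanks an isolated pulse with slow
  # counter-movement undershoot (its area balances the displacement), and
  # trims some of the pulse's own area; the movement itself is the single
  # positive x segment
  expect_true(all(segs$axis == "x"))
  main <- segs[segs$sign == 1L & segs$displacement > 0.05 * 0.3, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$displacement, 0.3, tolerance = 0.25)
  expect_true(all(segs$displacement[segs$sign == -1] < 0.5 * 0.3))
})

test_that("fragmentation increases anatomical segment rate with impairment", {
  rate_at <- function(th) {
    r <- simulate_subject(subject_spec("S", th, duration_s = 60, seed = 5))
    s <- subject_segments(r, "anatomical", use_truth_orientation = TRUE)
    n_reach <- sum(r$truth$events$kind == "linear")
    nrow(s) / n_reach
  }
  expect_gt(rate_at(0.7), rate_at(0))
})

test_that("primary direction recovers the movement axis", {
  u <- c(1, 2, -0.5); u <- u / sqrt(sum(u^2))
  t <- seq(0, 1, by = 0.02)
  prof <- minimum_jerk_velocity(0.3, 1, 50)$v
  v3 <- tibble::tibble(t = t, vx = prof * u[1], vy = prof * u[2], vz = prof * u[3])
  d <- primary_direction(v3)
  expect_equal(abs(sum(d * u)), 1, tolerance = 1e-9)
  expect_equal(attr(d, "explained"), 1, tolerance = 1e-9)
  # sign convention: mean projected velocity is non-negative
  expect_gte(mean(as.matrix(v3[, 2:4]) %*% d), 0)
  # orthogonal noise barely tilts the axis
  set.seed(4)
  w <- c(-2, 1, 0); w <- w / sqrt(sum(w^2))
  noisy <- v3
  noise <- rnorm(length(prof), 0, 0.05 * max(prof))
  noisy$vx <- noisy$vx + noise * w[1]
  noisy$vy <- noisy$vy + noise * w[2]
  noisy$vz <- noisy$vz + noise * w[3]
  expect_gt(abs(sum(primary_direction(noisy) * u)), 0.99)
  flat <- tibble::tibble(t = t, vx = 0, vy = 0, vz = 0)
  expect_error(primary_direction(flat), "degenerate")
})

test_that("linear segmentation isolates single reaches and fragmented ones", {
  fx <- reach_recording(amplitude = 0.3, duration = 1, axis = 2)
  iv <- tibble::tibble(start_s = fx$pulse_window[1], end_s = fx$pulse_window[2])
  segs <- linear_segments(fx$wrist, iv, q_wrist = fx$q_identity)
  main <- segs[segs$displacement > 0.05 * 0.3, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$axis, "primary")
  expect_equal(main$displacement, 0.3, tolerance = 0.25)
  # empty interval list
  expect_equal(nrow(linear_segments(fx$wrist, iv[0, ], q_wrist = fx$q_identity)), 0L)
  # three submovements separated by brief reversals: at least 3 segments
  fs <- 50
  pad <- rep(0, 2 * fs)
  p <- minimum_jerk_velocity(0.1, 0.6, fs)$v
  b <- -minimum_jerk_velocity(0.01, 0.2, fs)$v
  v1 <- c(pad, p, b, p, b, p, pad)
  vm <- cbind(v1, 0, 0)
  n <- length(v1)
  a1 <- c(0, diff(v1)) * fs
  rec <- imu_recording(tibble::tibble(
    t = (seq_len(n) - 1) / fs, ax = a1, ay = 0, az = 9.81,
    gx = 0, gy = 0, gz = 0), site = "wrist", fs = fs)
  iv3 <- tibble::tibble(start_s = 2, end_s = n / fs - 2)
  q_id <- matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE)
  segs3 <- linear_segments(rec, iv3, q_wrist = q_id)
  expect_gte(nrow(segs3), 3L)
  expect_gte(sum(segs3$sign == 1), 3L)
})

test_that("anatomical and linear boundaries agree on a pure axis-aligned reach", {
  fx <- reach_recording(amplitude = 0.3, duration = 1, axis = 1)
  a_segs <- anatomical_segments(fx$wrist, fx$sternum,
                                q_wrist = fx$q_identity, q_sternum = fx$q_identity,
                                second_lowpass = FALSE)
  iv <- tibble::tibble(start_s = fx$pulse_window[1] - 1, end_s = fx$pulse_window[2] + 1)
  l_segs <- linear_segments(fx$wrist, iv, q_wrist = fx$q_identity)
  a_main <- a_segs[which.max(a_segs$displacement), ]
  l_main <- l_segs[which.max(l_segs$displacement), ]
  expect_lte(abs(a_main$start_idx - l_main$start_idx), 1L)
  expect_lte(abs(a_main$end_idx - l_main$end_idx), 1L)
})

test_that("linear-method kinematics are invariant to a fixed global rotation", {
  fx <- reach_recording(amplitude = 0.25, duration = 1, axis = 1)
  iv <- tibble::tibble(start_s = fx$pulse_window[1] - 0.5, end_s = fx$pulse_window[2] + 0.5)
  base <- linear_segments(fx$wrist, iv, q_wrist = fx$q_identity)
  # rotate the whole recording by a fixed rotation (gravity must follow too,
  # so rotate the local-frame readings and hand the matching orientation in)
  qrot <- segmotor:::quat_from_axis_angle(c(1, 1, 0.3), 1.1)
  n <- nrow(fx$wrist)
  aw <- as.matrix(tibble::as_tibble(fx$wrist)[c("ax", "ay", "az")])
  rec_rot <- imu_recording(tibble::tibble(
    t = fx$wrist$t,
    ax = aw[, 1], ay = aw[, 2], az = aw[, 3],
    gx = 0, gy = 0, gz = 0), site = "wrist", fs = 50)
  q_rot_track <- matrix(rep(qrot, n), n, 4, byrow = TRUE)
  rot <- linear_segments(rec_rot, iv, q_wrist = q_rot_track)
  expect_equal(nrow(rot), nrow(base))
  expect_equal(rot$duration, base$duration, tolerance = 1e-9)
  expect_equal(rot$displacement, base$displacement, tolerance = 1e-6)
})
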