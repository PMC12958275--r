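# Shared fixtures, built in code and memoized for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small default cohort reused across files
fixture_cohort <- function(n = 6, seed = 3, duration_s = 90, ...) {
  memo(sprintf("coh_%d_%d_%g", n, seed, duration_s),
       simulate_cohort(n = n, seed = seed, duration_s = duration_s, ...))
}

fixture_segtab <- function(method = "anatomical") {
  memo(paste0("segtab_", method),
       cohort_segments(fixture_cohort(), method = method))
}

# ideal single-reach recording along one global axis: min-jerk pulse framed
# by rest, identity orientation, no noise
reach_recording <- function(amplitude = 0.3, duration = 1, axis = 1, fs = 50,
                            pad_s = 3) {
  pad <- rep(0, pad_s * fs)
  v1 <- c(pad, minimum_jerk_velocity(amplitude, duration, fs)$v, pad)
  v <- matrix(0, length(v1), 3)
  v[, axis] <- v1
  n <- nrow(v)
  t <- (seq_len(n) - 1) / fs
  a <- apply(v, 2, function(col) {
    g <- numeric(n)
    g[1] <- (col[2] - col[1]) * fs
    g[n] <- (col[n] - col[n - 1]) * fs
    g[2:(n - 1)] <- (col[3:n] - col[1:(n - 2)]) * fs / 2
    g
  })
  wrist <- imu_recording(
    tibble::tibble(t = t, ax = a[, 1], ay = a[, 2], az = a[, 3] + 9.81,
                   gx = 0, gy = 0, gz = 0), site = "wrist", fs = fs)
  sternum <- imu_recording(
    tibble::tibble(t = t, ax = 0, ay = 0, az = 9.81, gx = 0, gy = 0, gz = 0),
    site = "sternum", fs = fs)
  list(wrist = wrist, sternum = sternum, t = t, v = v,
       pulse_window = c(pad_s, pad_s + duration),
       q_identity = matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE))
}

# two separable window classes (different carrier frequencies under a
# Gaussian envelope) for detector tests
separable_windows <- function(n, seed, fs = 50, window_s = 3) {
  L <- window_s * fs
  set.seed(seed)
  mk <- function(label) {
    t <- seq_len(L)
    f <- if (label == 1) 2 else 6
    env <- exp(-(t - L / 2)^2 / (2 * (L / 7)^2))
    sapply(1:6, function(c) env * sin(2 * pi * f * t / L + stats::runif(1, 0, 6)) +
             stats::rnorm(L, 0, 0.05))
  }
  labels <- rep(0:1, length.out = n)
  tibble::tibble(start_idx = 1L, start_s = 0, end_s = window_s,
                 label = labels, data = lapply(labels, mk))
}

# brute-force sign-run segmentation oracle
oracle_sign_runs <- function(v, zero_tol = 1e-4) {
  s <- ifelse(abs(v) < zero_tol, 0L, ifelse(v > 0, 1L, -1L))
  runs <- list()
  i <- 1L
  n <- length(s)
  while (i <= n) {
    if (s[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(start = i, end = j, sign = s[i])
    i <- j + 1L
  }
  if (length(runs) == 0L) return(data.frame(start = integer(), end = integer(), sign = integer()))
  as.data.frame(do.call(rbind, runs))
}
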