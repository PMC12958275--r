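## Synthetic cohort generator.
##
## Movements are built from minimum-jerk submovements: straight ("linear")
## reaches are a single bell-shaped pulse along a random 3-D direction for an
## unimpaired subject, and fragment into several partially-overlapping pulses
## (with small corrective reversals and growing tremor) as the impairment
## level theta rises.  The wrist and sternum IMU streams are forward-simulated
## from the trajectory and ground-truth orientation tracks, so every
## downstream stage can be checked against generator truth.

GRAVITY <- 9.81

#' Evaluate code with a temporary RNG seed, restoring the caller's stream
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Minimum-jerk speed profile
#'
#' Closed-form speed of a point-to-point minimum-jerk movement:
#' \eqn{v(t) = (A/T)\,30(\tau^2 - 2\tau^3 + \tau^4)} with \eqn{\tau = t/T}.
#' The profile is non-negative, zero at both ends, peaks at
#' \eqn{15A/(8T)} at mid-movement, and integrates to the commanded
#' amplitude \eqn{A}.  Its mean-to-peak speed ratio is 8/15, the reference
#' value for the `speed_metric` smoothness feature.
#'
#' @param amplitude Displacement of the movement (m), > 0.
#' @param duration Movement duration (s), > 0.
#' @param fs Sample rate (Hz); `fs * duration` must cover at least 3 samples.
#' @return A tibble with columns `t` (s) and `v` (m/s).
#' @examples
#' prof <- minimum_jerk_velocity(0.3, 1, 50)
#' max(prof$v) # 15/8 * 0.3
#' @export
minimum_jerk_velocity <- function(amplitude, duration, fs) {
  if (!is.numeric(amplitude) || amplitude <= 0) stop("`amplitude` must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  if (fs * duration < 2) stop("`fs * duration` must cover at least 3 samples")
  n <- round(duration * fs) + 1L
  t <- seq(0, duration, length.out = n)
  tau <- t / duration
  v <- (amplitude / duration) * 30 * (tau^2 - 2 * tau^3 + tau^4)
  tibble::tibble(t = t, v = v)
}

.mj_pulse <- function(amplitude, duration, fs) {
  minimum_jerk_velocity(amplitude, duration, fs)$v
}

#' Specification of one synthetic subject
#'
#' @param subject_id Character id.
#' @param theta Impairment level in \[0, 1\]; 0 = unimpaired.
#' @param duration_s Total recording length (s).
#' @param fs Sample rate (Hz).
#' @param seed Integer seed; identical specs give bit-identical output.
#' @param task_templates Character vector of ADL task names cycled through
#'   during the recording (labels only; they do not change the movement
#'   statistics).
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, theta, duration_s = 180, fs = 50, seed = 1L,
                         task_templates = default_task_templates()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(theta) || theta < 0 || theta > 1) stop("`theta` must be in [0, 1]")
  if (duration_s <= 0) stop("`duration_s` must be > 0")
  if (fs <= 0) stop("`fs` must be > 0")
  structure(list(subject_id = subject_id, theta = theta, duration_s = duration_s,
                 fs = fs, seed = as.integer(seed),
                 task_templates = task_templates),
            class = "subject_spec")
}

#' Default ADL task template vocabulary
#' @return Character vector of task names.
#' @export
default_task_templates <- function() {
  c("drink_from_cup", "brush_hair", "fold_towel", "move_object_on_shelf",
    "open_door", "wipe_table", "don_doff_jacket", "turn_book_page",
    "pour_water", "use_phone", "eat_snack")
}

#' Map an impairment level to clinical assessment scores
#'
#' Emulates the monotone, noisy relation between underlying motor impairment
#' and standard upper-limb clinical measures: FMA-UE (0-66, higher = better),
#' WMFT performance time (s, higher = worse), WMFT-FAS and the two MAL scales
#' (0-5, higher = better).  Noise is Gaussian on the FMA-UE scale and scaled
#' proportionally for the 0-5 scales.
#'
#' @param theta Impairment in \[0, 1\].
#' @param noise_sd Noise standard deviation in FMA-UE score units.
#' @param seed Optional integer seed (uses the current RNG stream if `NULL`).
#' @return A named list with `fma_ue`, `wmft_pt_median`, `wmft_fas`,
#'   `mal_aou`, `mal_qom`.
#' @export
impairment_to_scores <- function(theta, noise_sd = 3, seed = NULL) {
  if (!is.numeric(theta) || theta < 0 || theta > 1) stop("`theta` must be in [0, 1]")
  draw <- function() {
    eps <- stats::rnorm(5, 0, noise_sd)
    s5 <- 5 / 66 # rescale FMA-scale noise onto the 0-5 scales
    list(
      fma_ue = min(max(66 * (1 - theta) + eps[1L], 0), 66),
      wmft_pt_median = max(1.5 + 28 * theta^1.6 + eps[2L] * 0.2, 0.5),
      wmft_fas = min(max(5 * (1 - theta) + eps[3L] * s5, 0), 5),
      mal_aou = min(max(5 * (1 - theta) + eps[4L] * s5, 0), 5),
      mal_qom = min(max(5 * (1 - theta) + eps[5L] * s5, 0), 5)
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

.grad_fs <- function(x, fs) {
  # central-difference time derivative, one-sided at the ends
  x <- as.matrix(x)
  n <- nrow(x)
  g <- x * 0
  g[1L, ] <- (x[2L, ] - x[1L, ]) * fs
  g[n, ] <- (x[n, ] - x[n - 1L, ]) * fs
  if (n > 2L) g[2:(n - 1L), ] <- (x[3:n, ] - x[1:(n - 2L), ]) * fs / 2
  g
}

.cumtrapz_fs <- function(x, fs) {
  x <- as.matrix(x)
  apply(x, 2L, function(col) pracma::cumtrapz(seq_along(col) / fs, col)[, 1L])
}

.random_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate one subject's recording session
#'
#' Builds a global-frame wrist velocity as a seeded sequence of straight
#' reaches, curved (multi-direction) movements and rest periods, then
#' forward-simulates both IMUs: wrist local acceleration is the trajectory
#' acceleration plus gravity rotated into a slowly drifting local frame, the
#' gyroscope reads the local-frame angular velocity, and the sternum stream
#' carries slow torso rotations.  White sensor noise is added last.
#'
#' Fragmentation with impairment: a reach at impairment `theta` is split into
#' `1 + floor(4 * theta)` forward minimum-jerk pulses separated by small
#' corrective reversals, its duration is stretched by `1 / (1 - 0.5 * theta)`,
#' and tremor (4-7 Hz) with amplitude proportional to `theta` is added during
#' movement.
#'
#' @param spec A [subject_spec()].
#' @param accel_noise_sd Accelerometer white-noise sd (m/s^2).
#' @param gyro_noise_sd Gyroscope white-noise sd (rad/s).
#' @param score_noise_sd Clinical-score noise sd (FMA-UE units).
#' @param tremor_scale Peak tremor velocity at `theta = 1` (m/s).
#' @return An object of class `subject_record`: a list with `wrist` and
#'   `sternum` IMU tibbles (`t, ax, ay, az, gx, gy, gz`), `linear_intervals`,
#'   `scores`, `theta`, and a `truth` list holding the ground-truth
#'   orientation tracks, global-frame velocity and event table.
#' @export
simulate_subject <- function(spec, accel_noise_sd = 0.05, gyro_noise_sd = 0.01,
                             score_noise_sd = 3, tremor_scale = 0.08) {
  stopifnot(inherits(spec, "subject_spec"))
  fs <- spec$fs
  theta <- spec$theta
  n <- round(spec$duration_s * fs) + 1L
  if (spec$duration_s < 5) stop("`duration_s` too short to place any task")
  with_seed(spec$seed, {
    t <- (seq_len(n) - 1L) / fs
    v_g <- matrix(0, n, 3L)
    events <- list()
    idx_of <- function(s) min(max(1L, round(s * fs) + 1L), n)
    add_pulse <- function(v, start_s, amplitude, dur, u) {
      i0 <- idx_of(start_s)
      prof <- .mj_pulse(amplitude, dur, fs)
      i1 <- min(n, i0 + length(prof) - 1L)
      keep <- seq_len(i1 - i0 + 1L)
      v[i0:i1, ] <- v[i0:i1, ] + outer(prof[keep], u)
      v
    }
    task_i <- 0L
    cur <- 0.5
    while (cur < spec$duration_s - 3) {
      task_i <- task_i + 1L
      task <- spec$task_templates[((task_i - 1L) %% length(spec$task_templates)) + 1L]
      kind <- sample(c("linear", "nonlinear", "rest"), 1L, prob = c(0.45, 0.35, 0.20))
      if (kind == "rest") {
        dur <- stats::runif(1, 0.8, 2.5)
        events[[length(events) + 1L]] <-
          tibble::tibble(kind = "rest", task = task, start_s = cur, end_s = cur + dur,
                         n_submovements = 0L, amplitude = 0)
        cur <- cur + dur
        next
      }
      # tremor/irregularity parameters are always drawn so the RNG stream
      # does not depend on theta; amplitudes are zero when theta = 0
      trem_f <- stats::runif(1, 4, 7)
      trem_ph <- stats::runif(3, 0, 2 * pi)
      trem_dir <- matrix(stats::rnorm(9), 3)
      irr_f <- stats::runif(1, 2, 3.5)
      irr_ph <- stats::runif(1, 0, 2 * pi)
      add_tremor <- function(v, s0, s1) {
        if (theta <= 0) return(v)
        seg <- idx_of(s0):idx_of(s1)
        env <- sin(pi * seq(0, 1, length.out = length(seg)))^2
        # velocity irregularity: a slow multiplicative modulation that makes
        # profiles peaky (degrades the mean-to-peak speed ratio) without
        # changing the path direction
        m <- 0.45 * theta
        v[seg, ] <- v[seg, ] *
          (1 + m * sin(2 * pi * irr_f * t[seg] + irr_ph))
        trem_amp <- tremor_scale * theta
        for (ax in 1:3) {
          d <- trem_dir[, ax] / sqrt(sum(trem_dir[, ax]^2))
          v[seg, ] <- v[seg, ] +
            outer(trem_amp * env * sin(2 * pi * trem_f * t[seg] + trem_ph[ax]), d) / 3
        }
        v
      }
      add_reach <- function(v, start_s, amp, dur, u, n_sub) {
        if (n_sub == 1L) return(add_pulse(v, start_s, amp, dur, u))
        # submovements come in pairs that overlap (multi-peaked, less smooth
        # profiles), and successive pairs are separated by short gaps
        # carrying small corrective reversals (genuine zero crossings)
        sizes <- rep(2L, n_sub %/% 2L)
        if (n_sub %% 2L == 1L) sizes <- c(sizes, 1L)
        n_groups <- length(sizes)
        # group span in units of the submovement duration: overlapped pulses
        # start 0.85 of a duration apart
        span_units <- sum(1 + 0.85 * (sizes - 1L)) + 0.3 * (n_groups - 1L)
        t_sub <- dur / span_units
        gap <- 0.3 * t_sub
        back_amp <- if (n_groups > 1L) 0.08 * theta * amp / (n_groups - 1L) else 0
        fwd_amp <- (amp + back_amp * (n_groups - 1L)) / n_sub
        on_g <- start_s
        for (g in seq_len(n_groups)) {
          for (j in seq_len(sizes[g])) {
            v <- add_pulse(v, on_g + (j - 1L) * 0.85 * t_sub, fwd_amp, t_sub, u)
          }
          on_g <- on_g + (1 + 0.85 * (sizes[g] - 1L)) * t_sub
          if (g < n_groups) {
            v <- add_pulse(v, on_g, back_amp, gap, -u)
            on_g <- on_g + gap
          }
        }
        v
      }
      if (kind == "linear") {
        # out-and-back reach pair: transporting to and retrieving from a
        # target are each a straight movement, and the workspace stays
        # bounded (little sub-0.1 Hz velocity content, as in real ADLs)
        amp <- stats::runif(1, 0.15, 0.45)
        t0 <- stats::runif(1, 0.7, 1.3)
        dwell <- stats::runif(1, 0.2, 0.7)
        u <- .random_unit3()
        dur <- t0 / (1 - 0.5 * theta)
        n_sub <- 1L + floor(4 * theta)
        v_g <- add_reach(v_g, cur, amp, dur, u, n_sub)
        v_g <- add_tremor(v_g, cur, cur + dur)
        back_start <- cur + dur + dwell
        v_g <- add_reach(v_g, back_start, amp, dur, -u, n_sub)
        v_g <- add_tremor(v_g, back_start, back_start + dur)
        events[[length(events) + 1L]] <-
          tibble::tibble(kind = "linear", task = task, start_s = cur, end_s = cur + dur,
                         n_submovements = n_sub, amplitude = amp)
        events[[length(events) + 1L]] <-
          tibble::tibble(kind = "linear", task = task, start_s = back_start,
                         end_s = back_start + dur, n_submovements = n_sub,
                         amplitude = amp)
        cur <- back_start + dur + stats::runif(1, 0.4, 1.2)
      } else {
        # curved movement: 2-3 pulses along different directions, staggered,
        # plus a closing pulse back to the start of the block
        n_p <- sample(2:3, 1L)
        block_end <- cur
        disp <- c(0, 0, 0)
        for (j in seq_len(n_p)) {
          amp <- stats::runif(1, 0.10, 0.30)
          dur <- stats::runif(1, 0.8, 1.4) / (1 - 0.5 * theta)
          on_j <- cur + (j - 1L) * dur * 0.5
          u <- .random_unit3()
          v_g <- add_pulse(v_g, on_j, amp, dur, u)
          disp <- disp + amp * u
          block_end <- max(block_end, on_j + dur)
        }
        ret_amp <- sqrt(sum(disp^2))
        ret_dur <- stats::runif(1, 0.8, 1.4) / (1 - 0.5 * theta)
        if (ret_amp > 1e-6) {
          v_g <- add_pulse(v_g, block_end, ret_amp, ret_dur, -disp / ret_amp)
          block_end <- block_end + ret_dur
        }
        v_g <- add_tremor(v_g, cur, block_end)
        events[[length(events) + 1L]] <-
          tibble::tibble(kind = "nonlinear", task = task, start_s = cur, end_s = block_end,
                         n_submovements = n_p + 1L, amplitude = NA_real_)
        cur <- block_end + stats::runif(1, 0.4, 1.2)
      }
    }
    events <- dplyr::bind_rows(events)
    a_g <- .grad_fs(v_g, fs)

    # ground-truth orientations: wrist starts with a random tilt (no yaw) and
    # drifts slowly; sternum sways and slowly yaws
    tilt_ax <- c(stats::rnorm(2), 0); tilt_ax <- tilt_ax / sqrt(sum(tilt_ax[1:2]^2))
    q0_w <- quat_from_axis_angle(tilt_ax, stats::runif(1, 0, 25 * pi / 180))
    wf <- stats::runif(3, 0.03, 0.10); wa <- stats::runif(3, 0.03, 0.10)
    wp <- stats::runif(3, 0, 2 * pi)
    om_w <- sapply(1:3, function(k) wa[k] * sin(2 * pi * wf[k] * t + wp[k]))
    q_w <- quat_integrate(om_w, fs, q0_w)

    sf <- stats::runif(3, 0.02, 0.05); sp <- stats::runif(3, 0, 2 * pi)
    om_s <- cbind(0.02 * sin(2 * pi * sf[1L] * t + sp[1L]),
                  0.02 * sin(2 * pi * sf[2L] * t + sp[2L]),
                  0.08 * sin(2 * pi * sf[3L] * t + sp[3L]))
    q_s <- quat_integrate(om_s, fs, c(1, 0, 0, 0))

    gz <- matrix(c(0, 0, GRAVITY), n, 3L, byrow = TRUE)
    a_w_local <- quat_rotate(quat_conjugate(q_w), a_g + gz)
    a_s_local <- quat_rotate(quat_conjugate(q_s), gz)

    wrist <- tibble::tibble(
      t = t,
      ax = a_w_local[, 1L] + stats::rnorm(n, 0, accel_noise_sd),
      ay = a_w_local[, 2L] + stats::rnorm(n, 0, accel_noise_sd),
      az = a_w_local[, 3L] + stats::rnorm(n, 0, accel_noise_sd),
      gx = om_w[, 1L] + stats::rnorm(n, 0, gyro_noise_sd),
      gy = om_w[, 2L] + stats::rnorm(n, 0, gyro_noise_sd),
      gz = om_w[, 3L] + stats::rnorm(n, 0, gyro_noise_sd)
    )
    sternum <- tibble::tibble(
      t = t,
      ax = a_s_local[, 1L] + stats::rnorm(n, 0, accel_noise_sd),
      ay = a_s_local[, 2L] + stats::rnorm(n, 0, accel_noise_sd),
      az = a_s_local[, 3L] + stats::rnorm(n, 0, accel_noise_sd),
      gx = om_s[, 1L] + stats::rnorm(n, 0, gyro_noise_sd),
      gy = om_s[, 2L] + stats::rnorm(n, 0, gyro_noise_sd),
      gz = om_s[, 3L] + stats::rnorm(n, 0, gyro_noise_sd)
    )
    linear_intervals <- events |>
      dplyr::filter(.data$kind == "linear") |>
      dplyr::transmute(start_s = .data$start_s, end_s = .data$end_s, kind = "linear")
    scores <- impairment_to_scores(theta, noise_sd = score_noise_sd)

    structure(list(
      subject_id = spec$subject_id,
      wrist = imu_recording(wrist, site = "wrist", fs = fs),
      sternum = imu_recording(sternum, site = "sternum", fs = fs),
      linear_intervals = linear_intervals,
      scores = scores,
      theta = theta,
      fs = fs,
      duration_s = spec$duration_s,
      spec = spec,
      truth = list(q_wrist = q_w, q_sternum = q_s, v_global = v_g,
                   a_global = a_g, events = events)
    ), class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id,
      sprintf(" | %.0f s @ %g Hz | theta = %.2f | %d linear intervals\n",
              x$duration_s, x$fs, x$theta, nrow(x$linear_intervals)))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' @param n Number of subjects.
#' @param seed Cohort seed; per-subject seeds and impairment levels are drawn
#'   from it, so the whole cohort is a pure function of its arguments.
#' @param duration_s Recording length per subject (s).
#' @param theta_range Range of the uniform impairment draw.
#' @param fs Sample rate (Hz).
#' @param ... Passed to [simulate_subject()] (noise levels etc.).
#' @return A list of `subject_record` objects.
#' @export
simulate_cohort <- function(n = 17, seed = 1L, duration_s = 180,
                            theta_range = c(0.05, 0.9), fs = 50, ...) {
  stopifnot(n >= 1)
  pars <- with_seed(seed, {
    list(theta = stats::runif(n, theta_range[1L], theta_range[2L]),
         seeds = sample.int(.Machine$integer.max %/% 2L, n))
  })
  lapply(seq_len(n), function(i) {
    sp <- subject_spec(sprintf("S%02d", i), theta = pars$theta[i],
                       duration_s = duration_s, fs = fs, seed = pars$seeds[i])
    simulate_subject(sp, ...)
  })
}

#' Clinical score table for a cohort
#'
#' @param cohort List of `subject_record`s.
#' @return A tibble with one row per subject: `subject_id`, `theta` and the
#'   five clinical scores.
#' @export
cohort_scores <- function(cohort) {
  purrr::map_dfr(cohort, function(r)
    tibble::tibble(subject_id = r$subject_id, theta = r$theta,
                   fma_ue = r$scores$fma_ue,
                   wmft_pt_median = r$scores$wmft_pt_median,
                   wmft_fas = r$scores$wmft_fas,
                   mal_aou = r$scores$mal_aou,
                   mal_qom = r$scores$mal_qom))
}
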