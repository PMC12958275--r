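## Movement segmentation: velocity zero-crossing decomposition under the
## anatomical (trunk-frame, per-axis) and linear (primary-direction)
## strategies, with duration / travelled-distance quality filters.

#' Decompose a one-axis velocity series at zero crossings
#'
#' Segments are maximal runs of same-sign samples between sign changes.
#' Samples with magnitude below `zero_tol` count as zero: they terminate the
#' current segment and belong to neither neighbour, so the returned segments
#' exactly tile the non-zero support of the series.
#'
#' @param v Numeric velocity series (m/s).
#' @param fs Sample rate (Hz).
#' @param zero_tol Magnitude below which a sample is treated as a crossing.
#' @param axis Label stored with each segment (`"x"`, `"y"`, `"z"` or
#'   `"primary"`).
#' @param offset Index offset added to `start_idx` / `end_idx` (used when
#'   `v` is a slice of a longer recording).
#' @return A tibble of movement segments: `axis`, `start_idx`, `end_idx`
#'   (half-open sample range), `duration` (s), `displacement` (m, absolute
#'   trapezoid integral), `sign`, and the velocity profile as a list column
#'   `profile`.
#' @export
segment_zero_crossings <- function(v, fs, zero_tol = 1e-4, axis = "x",
                                   offset = 0L) {
  v <- as.numeric(v)
  stopifnot(all(is.finite(v)))
  s <- ifelse(abs(v) < zero_tol, 0L, ifelse(v > 0, 1L, -1L))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(empty_segments())
  starts <- starts[keep]; ends <- ends[keep]; signs <- r$values[keep]
  profs <- purrr::map2(starts, ends, function(i, j) v[i:j])
  tibble::tibble(
    axis = axis,
    start_idx = starts + offset,
    end_idx = ends + 1L + offset,
    duration = (ends - starts + 1L) / fs,
    displacement = purrr::map_dbl(profs, function(p) {
      if (length(p) < 2L) return(0)
      abs(pracma::trapz(seq_along(p) / fs, p))
    }),
    sign = signs,
    profile = profs
  )
}

empty_segments <- function() {
  tibble::tibble(axis = character(), start_idx = integer(), end_idx = integer(),
                 duration = numeric(), displacement = numeric(), sign = integer(),
                 profile = list())
}

#' Remove implausibly short or small movement segments
#'
#' Keeps segments with duration strictly greater than `min_duration`
#' (segments of exactly 50 ms are removed) and travelled distance of at
#' least `min_displacement` (the 1 mm boundary is retained).  Sub-threshold
#' segments are attributed to sensor noise.
#'
#' @param segs Segment tibble from [segment_zero_crossings()].
#' @param min_duration Duration threshold (s), exclusive. Default 0.05.
#' @param min_displacement Displacement threshold (m), inclusive.
#'   Default 0.001.
#' @return The filtered segment tibble.
#' @export
filter_segments <- function(segs, min_duration = 0.05, min_displacement = 0.001) {
  dplyr::filter(segs, .data$duration > min_duration,
                .data$displacement >= min_displacement)
}

#' Anatomical movement segmentation
#'
#' Runs the full preprocessing chain to trunk-frame wrist velocity, then
#' decomposes each anatomical axis independently at velocity zero crossings,
#' pools the three axes and applies the quality filters.
#'
#' @param wrist,sternum Synchronized [imu_recording()]s.
#' @param q_wrist,q_sternum Optional ground-truth orientation tracks.
#' @param zero_tol Zero-crossing tolerance (m/s).
#' @param min_duration,min_displacement Quality-filter thresholds.
#' @param ... Passed to [body_velocity()].
#' @return A segment tibble (axes `x`, `y`, `z`) sorted by onset.
#' @export
anatomical_segments <- function(wrist, sternum, q_wrist = NULL, q_sternum = NULL,
                                zero_tol = 1e-4, min_duration = 0.05,
                                min_displacement = 0.001, ...) {
  fs <- imu_fs(wrist)
  v <- body_velocity(wrist, sternum, q_wrist = q_wrist, q_sternum = q_sternum, ...)
  segs <- dplyr::bind_rows(
    segment_zero_crossings(v$vx, fs, zero_tol, axis = "x"),
    segment_zero_crossings(v$vy, fs, zero_tol, axis = "y"),
    segment_zero_crossings(v$vz, fs, zero_tol, axis = "z")
  )
  segs <- filter_segments(segs, min_duration, min_displacement)
  dplyr::arrange(segs, .data$start_idx, .data$axis)
}

#' Primary movement direction by principal component analysis
#'
#' First principal axis of the 3 x 3 covariance of the velocity samples in a
#' window, unit norm, with the sign fixed so the mean projected velocity is
#' non-negative.
#'
#' @param v3 Tibble `t, vx, vy, vz`.
#' @param window Optional `c(start_s, end_s)` restricting the samples used.
#' @return A unit 3-vector with attribute `explained` (variance ratio of the
#'   first component).
#' @export
primary_direction <- function(v3, window = NULL) {
  m <- .axis_mat(v3, c("vx", "vy", "vz"))
  if (!is.null(window)) {
    keep <- v3$t >= window[1L] & v3$t < window[2L]
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("degenerate input: window has fewer than 3 samples")
  cv <- stats::cov(m)
  if (sum(diag(cv)) < 1e-16) stop("degenerate input: zero-variance window")
  e <- eigen(cv, symmetric = TRUE)
  u <- e$vectors[, 1L]
  if (mean(m %*% u) < 0) u <- -u
  attr(u, "explained") <- e$values[1L] / sum(e$values)
  u
}

#' Linear movement segmentation
#'
#' For each straight-movement interval (annotated or detector-predicted),
#' computes global-frame wrist velocity, projects it onto the interval's
#' principal direction, and decomposes the projection at zero crossings.
#' Intervals too short or with no movement variance are skipped with a
#' warning.
#'
#' @param wrist Wrist [imu_recording()].
#' @param intervals Tibble with `start_s`, `end_s`.
#' @param q_wrist Optional ground-truth wrist orientation.
#' @param zero_tol,min_duration,min_displacement As in
#'   [anatomical_segments()].
#' @param v_global Optional precomputed global-frame velocity (reused across
#'   calls on the same recording).
#' @return A segment tibble with axis `"primary"`; `start_idx` / `end_idx`
#'   index the full recording.
#' @export
linear_segments <- function(wrist, intervals, q_wrist = NULL, zero_tol = 1e-4,
                            min_duration = 0.05, min_displacement = 0.001,
                            v_global = NULL) {
  fs <- imu_fs(wrist)
  if (is.null(v_global)) v_global <- global_velocity(wrist, q_wrist = q_wrist)
  if (nrow(intervals) == 0L) return(empty_segments())
  out <- purrr::pmap(list(intervals$start_s, intervals$end_s), function(s0, s1) {
    keep <- which(v_global$t >= s0 & v_global$t < s1)
    if (length(keep) < 3L) {
      warning(sprintf("skipping degenerate interval [%.2f, %.2f)", s0, s1))
      return(empty_segments())
    }
    m <- .axis_mat(v_global[keep, ], c("vx", "vy", "vz"))
    if (sum(apply(m, 2L, stats::var)) < 1e-16) {
      warning(sprintf("skipping zero-variance interval [%.2f, %.2f)", s0, s1))
      return(empty_segments())
    }
    u <- primary_direction(v_global[keep, ])
    proj <- as.numeric(m %*% u)
    segment_zero_crossings(proj, fs, zero_tol, axis = "primary",
                           offset = keep[1L] - 1L)
  })
  segs <- dplyr::bind_rows(out)
  segs <- filter_segments(segs, min_duration, min_displacement)
  dplyr::arrange(segs, .data$start_idx)
}
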