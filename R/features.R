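## Per-segment kinematic features and subject-level aggregation.

.seg_feature_names <- c("v_mean", "v_std", "v_max", "v_rms", "v_cv",
                        "a_meanabs", "a_max", "j_meanabs", "j_max",
                        "displacement", "duration", "skewness", "n_peaks",
                        "speed_metric", "jerk_metric")
.agg_names <- c("mean", "std", "iqr", "p10", "p50", "p90")

#' Count local maxima with a prominence floor
#'
#' A sample is a peak if it exceeds both neighbours; its prominence is the
#' height above the higher of the two minima separating it from larger
#' values (or the series edge).
#' @noRd
.count_peaks <- function(s, min_prom_frac = 0.05) {
  n <- length(s)
  if (n < 3L) return(if (n > 0L && which.max(s) != 0L) 1L else 0L)
  is_peak <- which(s[2:(n - 1L)] > s[1:(n - 2L)] & s[2:(n - 1L)] >= s[3:n]) + 1L
  if (length(is_peak) == 0L) return(1L) # monotone rise/fall: single extreme
  floor_prom <- min_prom_frac * max(s)
  count <- 0L
  for (p in is_peak) {
    left <- s[1:p]; right <- s[p:n]
    hi_l <- which(left > s[p]); hi_r <- which(right > s[p])
    base_l <- if (length(hi_l)) min(left[max(hi_l):p]) else min(left)
    base_r <- if (length(hi_r)) min(right[1:min(hi_r)]) else min(right)
    prom <- s[p] - max(base_l, base_r)
    if (prom >= floor_prom) count <- count + 1L
  }
  max(count, 1L)
}

#' Temporal skewness of a speed profile
#'
#' Third standardized moment of time weighted by the (non-negative) speed
#' curve, i.e. the asymmetry of the profile's shape over time; exactly zero
#' for a time-symmetric bell.
#' @noRd
.profile_skewness <- function(s) {
  w <- s / sum(s)
  t <- seq_along(s)
  mu <- sum(w * t)
  s2 <- sum(w * (t - mu)^2)
  if (s2 < 1e-12) return(0)
  sum(w * (t - mu)^3) / s2^1.5
}

#' Kinematic features of one movement segment
#'
#' Velocity statistics are computed on speed (`|v|`; segments are
#' sign-constant), acceleration and jerk by first and second finite
#' differences of the profile scaled by `fs`.  Smoothness measures:
#' `speed_metric` = mean speed / peak speed (8/15 for an ideal minimum-jerk
#' bell), `jerk_metric` = -mean |jerk| / peak speed, `skewness` = temporal
#' asymmetry of the speed curve, `n_peaks` = local maxima of speed with
#' prominence at least 5% of the segment maximum.
#'
#' @param profile Numeric velocity profile of one segment (m/s), or a one-row
#'   segment tibble.
#' @param fs Sample rate (Hz).
#' @param min_peak_prominence Prominence floor for `n_peaks`, as a fraction
#'   of peak speed.
#' @return A one-row tibble with 15 named features.
#' @export
segment_features <- function(profile, fs, min_peak_prominence = 0.05) {
  if (is.data.frame(profile)) profile <- profile$profile[[1L]]
  tibble::as_tibble(as.list(.segment_feature_vec(as.numeric(profile), fs,
                                                 min_peak_prominence)))
}

.segment_feature_vec <- function(v, fs, min_peak_prominence = 0.05) {
  if (length(v) < 3L) stop("segment profile must have at least 3 samples")
  s <- abs(v)
  a <- diff(v) * fs
  j <- diff(v, differences = 2L) * fs^2
  peak <- max(s)
  # time-averages by trapezoid so the discrete mean matches the continuous
  # definition (mean speed of an ideal bell = 8/15 of its peak)
  tmean <- function(x) {
    n <- length(x)
    if (n < 2L) return(mean(x))
    (sum(x) - (x[1L] + x[n]) / 2) / (n - 1L)
  }
  v_mean <- tmean(s)
  j_meanabs <- tmean(abs(j))
  c(v_mean = v_mean,
    v_std = stats::sd(s),
    v_max = peak,
    v_rms = sqrt(tmean(s^2)),
    v_cv = stats::sd(s) / v_mean,
    a_meanabs = tmean(abs(a)),
    a_max = max(abs(a)),
    j_meanabs = j_meanabs,
    j_max = max(abs(j)),
    displacement = abs(sum(v) - (v[1L] + v[length(v)]) / 2) / fs,
    duration = length(v) / fs,
    skewness = .profile_skewness(s),
    n_peaks = as.numeric(.count_peaks(s, min_peak_prominence)),
    speed_metric = v_mean / peak,
    jerk_metric = -j_meanabs / peak)
}

#' Per-segment feature table
#'
#' @param segs Segment tibble.
#' @param fs Sample rate (Hz).
#' @return A tibble with one row of [segment_features()] per segment.
#' @export
segment_feature_table <- function(segs, fs) {
  if (nrow(segs) == 0L) {
    return(tibble::as_tibble(stats::setNames(
      as.list(rep(NA_real_, length(.seg_feature_names))), .seg_feature_names))[0, ])
  }
  m <- t(vapply(segs$profile, .segment_feature_vec,
                numeric(length(.seg_feature_names)), fs = fs))
  tibble::as_tibble(as.data.frame(m))
}

#' Subject-level feature vector names, in stable order
#' @return Character vector of the 91 feature names.
#' @export
subject_feature_names <- function() {
  c(as.vector(t(outer(.seg_feature_names, .agg_names, paste, sep = "_"))),
    "segments_per_second")
}

#' Aggregate per-segment features to the subject level
#'
#' For each of the 15 per-segment features, computes the mean, standard
#' deviation, interquartile range and 10th/50th/90th percentiles across
#' segments, plus the number of segments per second of analyzed recording:
#' 15 x 6 + 1 = 91 named values in a stable order.
#'
#' @param segs Segment tibble (at least 2 segments).
#' @param fs Sample rate (Hz).
#' @param analyzed_duration Duration of the analyzed time-series (s).
#' @return A one-row tibble with the 91 subject-level features.
#' @export
aggregate_features <- function(segs, fs, analyzed_duration) {
  if (nrow(segs) < 2L) stop("need at least 2 segments to aggregate (std undefined)")
  ft <- segment_feature_table(segs, fs)
  agg <- lapply(.seg_feature_names, function(f) {
    x <- ft[[f]]
    q <- stats::quantile(x, c(0.10, 0.50, 0.90), names = FALSE)
    stats::setNames(
      c(mean(x), stats::sd(x), stats::IQR(x), q),
      paste(f, .agg_names, sep = "_"))
  })
  out <- c(unlist(agg), segments_per_second = nrow(segs) / analyzed_duration)
  tibble::as_tibble(as.list(out))[subject_feature_names()]
}
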