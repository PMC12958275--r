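## Reliability and validity statistics: ICC(3,1), Spearman correlation,
## Steiger's z for dependent correlations, NRMSE, and the temporal
## split-half reliability protocol.

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measurement, consistency ICC for two
#' raters/sessions, from the standard ANOVA decomposition:
#' \eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E)} with k = 2.  Consistency form:
#' a fixed shift between sessions does not reduce the coefficient.
#'
#' @param x,y Paired measurements (one value per subject in each session).
#' @return The ICC as a single number; `NA` with a warning when the
#'   between-subject variance is zero (coefficient undefined).
#' @export
icc_3_1 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows < 1e-300) {
    warning("zero between-subject variance: ICC undefined")
    return(NA_real_)
  }
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties get average ranks).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return The correlation coefficient; `NA` with a warning for constant
#'   input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Steiger's z-test for two dependent correlations sharing one variable
#'
#' Tests H0: rho(1,2) = rho(1,3) given the correlation r23 between the two
#' non-shared variables, using Fisher z-transforms and the asymptotic
#' covariance evaluated at the pooled correlation (Steiger 1980).
#'
#' @param r12,r13 The two correlations being compared.
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 4).
#' @return A list with `z` and the two-sided normal `p`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must be strictly inside (-1, 1)")
  if (n < 4) stop("need n >= 4")
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  # covariance of the two dependent correlations at the pooled value
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s <- psi / (1 - rbar^2)^2
  if (s >= 1) stop("correlation triple is not consistent (covariance term >= 1)")
  z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Normalized root-mean-square error (percent of the reference range)
#'
#' @param estimate,truth Numeric vectors of equal length (n >= 2).
#' @return RMSE divided by `diff(range(truth))`, times 100.
#' @export
nrmse <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth), length(truth) >= 2L)
  rng <- diff(range(truth))
  if (rng == 0) stop("truth has zero range")
  sqrt(mean((estimate - truth)^2)) / rng * 100
}

#' Per-feature split-half reliability from two half-cohort feature tables
#'
#' @param h1,h2 Feature tibbles (one row per subject, matching order) from
#'   the first and second temporal halves; a `subject_id` column is ignored.
#' @param threshold Reliability cut-off; features with ICC(3,1) >= threshold
#'   (inclusive) are flagged reliable.
#' @return A tibble `feature, icc, reliable`.
#' @export
feature_reliability <- function(h1, h2, threshold = 0.75) {
  feats <- setdiff(intersect(names(h1), names(h2)), "subject_id")
  icc <- purrr::map_dbl(feats, function(f) {
    suppressWarnings(tryCatch(icc_3_1(h1[[f]], h2[[f]]), error = function(e) NA_real_))
  })
  tibble::tibble(feature = feats, icc = icc,
                 reliable = !is.na(icc) & icc >= threshold)
}

#' Temporal split-half reliability of the feature pipeline
#'
#' Splits each subject's recording at its temporal midpoint, reruns the
#' chosen segmentation and feature pipeline independently on each half, and
#' computes the across-subject ICC(3,1) of every feature between halves.
#' Subjects whose halves yield fewer than 2 segments are excluded with a
#' warning.
#'
#' @param cohort List of `subject_record`s.
#' @param method `"anatomical"`, `"linear_true"` or `"linear_detected"`.
#' @param threshold Reliability cut-off (inclusive), default 0.75.
#' @param detected_intervals For `linear_detected`: named list (by subject
#'   id) of predicted interval tibbles.
#' @param ... Passed to the segmentation pipeline (e.g.
#'   `use_truth_orientation = TRUE`).
#' @return An object of class `split_half_result`: list with `icc` (tibble
#'   `feature, icc, reliable`), `half1`, `half2` feature tables and
#'   `threshold`.
#' @export
split_half_reliability <- function(cohort, method = c("anatomical", "linear_true",
                                                      "linear_detected"),
                                   threshold = 0.75, detected_intervals = NULL, ...) {
  method <- match.arg(method)
  tabs <- cohort_feature_tables(cohort, method = method, halves_only = TRUE,
                                detected_intervals = detected_intervals, ...)
  icc <- feature_reliability(tabs$half1, tabs$half2, threshold = threshold)
  structure(list(icc = icc, half1 = tabs$half1, half2 = tabs$half2,
                 threshold = threshold, method = method),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("<split_half_result> method = %s | %d/%d features reliable (ICC >= %.2f)\n",
              x$method, sum(x$icc$reliable), nrow(x$icc), x$threshold))
  invisible(x)
}
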