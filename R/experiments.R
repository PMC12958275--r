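## Sensitivity experiments on the anatomical pipeline: segment subsampling
## (data-quantity effect) and the linear vs non-linear movement-type split.

.sample_segments <- function(segtab, p, seed) {
  if (p >= 100) return(segtab)
  sampled <- with_seed(seed, {
    segtab$segments |>
      dplyr::group_by(.data$subject_id, .data$half) |>
      dplyr::slice_sample(prop = p / 100) |>
      dplyr::ungroup()
  })
  list(segments = sampled, durations = segtab$durations, fs = segtab$fs)
}

#' Segment-subsampling experiment
#'
#' For each proportion `p`, independently samples `p`% of each subject's
#' movement segments from the full set and from each temporal half, reruns
#' reliability filtering and (optionally) the nested-LOSOCV assessment, and
#' repeats with fresh sampling seeds.  `p = 100` keeps every segment, so it
#' reproduces the full pipeline exactly.
#'
#' @param cohort List of `subject_record`s.
#' @param segtab Precomputed [cohort_segments()] output for the anatomical
#'   method (computed when `NULL`).
#' @param p_grid Percentages of segments to keep.
#' @param repeats Sampling repeats per `p` (default 5).
#' @param seed Base seed; sampling seeds are derived per cell, the model
#'   seed is held fixed so `p = 100` matches [assess_cohort()] run with the
#'   same `seed`.
#' @param run_model Run the nested-LOSOCV assessment per cell (otherwise
#'   only reliability is computed).
#' @param icc_threshold,lr_grid,epochs As in [assess_cohort()].
#' @param ... Passed to [cohort_segments()] when `segtab` is `NULL`.
#' @return A tibble with one row per `(p, repeat)`: `n_reliable` and, when
#'   the model is run, `rho_bar`, `rho_fma`, `icc`.
#' @export
subsample_experiment <- function(cohort, segtab = NULL,
                                 p_grid = seq(10, 100, by = 10), repeats = 5L,
                                 seed = 1L, run_model = TRUE,
                                 icc_threshold = 0.75,
                                 lr_grid = 10^seq(-4, -2, length.out = 5),
                                 epochs = 30L, ...) {
  if (is.null(segtab)) segtab <- cohort_segments(cohort, method = "anatomical", ...)
  scores <- cohort_scores(cohort)
  cells <- tidyr::expand_grid(p = p_grid, rep = seq_len(repeats))
  purrr::pmap_dfr(cells, function(p, rep) {
    samp_seed <- seed + 7919L * rep + round(p)
    st <- .sample_segments(segtab, p, samp_seed)
    row <- tibble::tibble(p = p, rep = rep, n_reliable = NA_integer_,
                          rho_bar = NA_real_, rho_fma = NA_real_, icc = NA_real_)
    tabs <- tryCatch(suppressWarnings(features_from_segments(st)),
                     error = function(e) NULL)
    if (is.null(tabs) || nrow(tabs$half1) < 5L) {
      warning(sprintf("p = %g, repeat %d skipped: too few segments", p, rep))
      return(row)
    }
    rel <- feature_reliability(tabs$half1, tabs$half2, threshold = icc_threshold)
    row$n_reliable <- sum(rel$reliable)
    if (run_model && row$n_reliable > 0L && !is.null(tabs$full)) {
      keep <- rel$feature[rel$reliable]
      res <- tryCatch(
        nested_losocv(tabs$full[c("subject_id", keep)],
                      scores[scores$subject_id %in% tabs$full$subject_id, ],
                      half1 = tabs$half1[c("subject_id", keep)],
                      half2 = tabs$half2[c("subject_id", keep)],
                      lr_grid = lr_grid, seed = seed, epochs = epochs),
        error = function(e) NULL)
      if (!is.null(res)) {
        row$rho_bar <- res$rho_bar
        row$rho_fma <- res$validity$rho[res$validity$measure == "fma_ue"]
        row$icc <- res$icc
      }
    }
    row
  })
}

#' Classify anatomical segments as linear- or non-linear-derived
#'
#' A segment is assigned to the linear group when the majority (> 50%) of
#' its time span lies inside the annotated linear-movement intervals.
#'
#' @param segments Segment tibble with `start_s`, `end_s`, `subject_id`.
#' @param intervals_by_subject Named list of interval tibbles.
#' @return The segment tibble with a `movement_type` column
#'   (`"linear"` / `"nonlinear"`).
#' @export
classify_segment_movement <- function(segments, intervals_by_subject) {
  if (nrow(segments) == 0L) {
    segments$movement_type <- character()
    return(segments)
  }
  ov <- purrr::pmap_dbl(
    list(segments$subject_id, segments$start_s, segments$end_s),
    function(sid, s0, s1) {
      iv <- intervals_by_subject[[sid]]
      if (is.null(iv) || nrow(iv) == 0L) return(0)
      sum(pmax(0, pmin(s1, iv$end_s) - pmax(s0, iv$start_s)))
    })
  segments$movement_type <- ifelse(ov > 0.5 * (segments$end_s - segments$start_s),
                                   "linear", "nonlinear")
  segments
}

#' Movement-type split of the anatomical assessment
#'
#' Partitions the anatomical movement segments into those derived from
#' annotated linear movements and all others, and runs the full reliability
#' + nested-LOSOCV assessment independently on each group.
#'
#' @inheritParams subsample_experiment
#' @return A list with `linear` and `nonlinear` `cohort_result`s and the
#'   classified segment table `segments`.
#' @export
movement_type_split <- function(cohort, segtab = NULL, seed = 1L,
                                icc_threshold = 0.75,
                                lr_grid = 10^seq(-4, -2, length.out = 5),
                                epochs = 30L, ...) {
  if (is.null(segtab)) segtab <- cohort_segments(cohort, method = "anatomical", ...)
  ints <- stats::setNames(lapply(cohort, function(r) r$linear_intervals),
                          vapply(cohort, function(r) r$subject_id, ""))
  seg <- classify_segment_movement(segtab$segments, ints)
  scores <- cohort_scores(cohort)
  run_group <- function(type) {
    sub <- dplyr::filter(seg, .data$movement_type == type)
    if (nrow(sub) == 0L) stop("empty ", type, " segment group")
    st <- list(segments = sub, durations = segtab$durations, fs = segtab$fs)
    tabs <- suppressWarnings(features_from_segments(st))
    rel <- feature_reliability(tabs$half1, tabs$half2, threshold = icc_threshold)
    keep <- rel$feature[rel$reliable]
    if (length(keep) == 0L) stop("no reliable features in the ", type, " group")
    res <- nested_losocv(tabs$full[c("subject_id", keep)],
                         scores[scores$subject_id %in% tabs$full$subject_id, ],
                         half1 = tabs$half1[c("subject_id", keep)],
                         half2 = tabs$half2[c("subject_id", keep)],
                         lr_grid = lr_grid, seed = seed, epochs = epochs)
    res$reliability <- rel
    res$method <- paste0("anatomical_", type)
    res
  }
  list(linear = run_group("linear"), nonlinear = run_group("nonlinear"),
       segments = seg)
}
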