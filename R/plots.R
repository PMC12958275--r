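## ggplot2 views of the main result objects.

#' Plot a velocity series with its movement segments
#'
#' @param v Tibble `t` plus velocity columns (`vx, vy, vz` or a single
#'   axis).
#' @param segs Segment tibble with `start_s`, `end_s` (e.g. from
#'   [subject_segments()]).
#' @param axis Which velocity column to draw.
#' @return A ggplot object.
#' @export
plot_segments <- function(v, segs, axis = "vx") {
  ggplot2::ggplot(v, ggplot2::aes(x = .data$t, y = .data[[axis]])) +
    ggplot2::geom_rect(
      data = segs,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf,
                   fill = factor(.data$sign)),
      alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`-1` = "#d95f02", `1` = "#1b9e77"),
                               name = "sign") +
    ggplot2::labs(x = "time (s)", y = "velocity (m/s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.split_half_result <- function(object, ...) {
  icc <- dplyr::arrange(object$icc, .data$icc)
  icc$feature <- factor(icc$feature, levels = icc$feature)
  ggplot2::ggplot(icc, ggplot2::aes(x = .data$icc, y = .data$feature,
                                    colour = .data$reliable)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "grey60")) +
    ggplot2::labs(x = "split-half ICC(3,1)", y = NULL,
                  title = sprintf("Feature reliability (%s)", object$method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' @export
autoplot.cohort_result <- function(object, ...) {
  df <- dplyr::left_join(object$estimates, object$scores, by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fma_ue, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "FMA-UE", y = "estimated motor status [0, 1]",
                  subtitle = sprintf("Spearman rho = %.2f | output ICC = %.2f",
                                     object$validity$rho[object$validity$measure == "fma_ue"],
                                     object$icc)) +
    ggplot2::theme_minimal()
}

#' Plot subsampling-experiment curves
#'
#' @param results Tibble from [subsample_experiment()].
#' @return A ggplot object showing the mean reliable-feature count (and
#'   validity, when present) against the sampled percentage.
#' @export
plot_subsample_curves <- function(results) {
  sm <- results |>
    dplyr::group_by(.data$p) |>
    dplyr::summarise(dplyr::across(c("n_reliable", "rho_bar", "icc"),
                                   ~ mean(.x, na.rm = TRUE)), .groups = "drop") |>
    tidyr::pivot_longer(-"p", names_to = "quantity")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$p, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "% of movement segments kept", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
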