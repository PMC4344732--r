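#' Plot an area profile
#'
#' @param object An `icv_profile`.
#' @param ... Unused.
#' @return A ggplot: area (mm^2) against slice position (mm).
#' @export
autoplot.icv_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$position_mm, y = .data$area_mm2)
  ) +
    ggplot2::geom_area(fill = "grey85", colour = "grey30") +
    ggplot2::labs(
      x = "position (mm)", y = expression(area ~ (mm^2)),
      title = sprintf("%s area profile, subject %s",
                      profile_orientation(object), profile_subject(object))
    ) +
    ggplot2::theme_minimal()
}

#' Percentile curves of the validity metrics
#'
#' One panel per orientation (rows) and metric (columns), percentile curves
#' against linear spacing, coloured by interpolation method — the standard
#' way of reading how estimate validity decays as slices get sparser.
#'
#' @param object An `icv_validity` from [evaluate_validity()].
#' @param metrics Metrics to show (default ICC, Pearson, Jaccard and signed
#'   percentage error).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.icv_validity <- function(object,
                                  metrics = c("icc", "pearson", "jaccard",
                                              "pct_error"),
                                  ...) {
  df <- object$percentiles %>%
    filter(.data$metric %in% metrics) %>%
    mutate(metric = factor(.data$metric, levels = metrics))
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$spacing_mm, y = .data$value, colour = .data$method,
      group = interaction(.data$method, .data$percentile)
    )
  ) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_grid(orientation ~ metric, scales = "free_y") +
    ggplot2::labs(
      x = "linear spacing (mm)", y = "percentile value", colour = "method",
      title = "Validity of sparse-slice ICV estimates",
      subtitle = sprintf(
        "5th/25th/50th/75th/95th percentiles over %d offset combinations",
        object$config$count
      )
    ) +
    ggplot2::theme_minimal()
}

#' Paired constant-vs-spline error differences
#'
#' Mean and 95% confidence interval of the per-subject MAPE difference
#' (piecewise constant minus cubic spline) against linear spacing; positive
#' values mean the spline improves on the constant interpolation.
#'
#' @param paired The `$paired` table of an [evaluate_validity()] result, or
#'   an `icv_validity` object, or [compare_interpolators()] output.
#' @return A ggplot.
#' @export
plot_interpolator_comparison <- function(paired) {
  if (inherits(paired, "icv_validity")) paired <- paired$paired
  ggplot2::ggplot(
    paired,
    ggplot2::aes(x = .data$spacing_mm, y = .data$mean_diff,
                 colour = .data$orientation)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::labs(
      x = "linear spacing (mm)",
      y = "MAPE difference, constant - spline (% points)",
      colour = "orientation",
      title = "Improvement from cubic spline over piecewise constant"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
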