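#' Bland-Altman plot for one variable
#'
#' Per-pair differences against per-pair means with the bias line (solid)
#' and the 1.96-SD limits of agreement (dashed).
#'
#' @inheritParams bland_altman
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, variable = "ci", stratum = "overall",
                              orientation = "ref_minus_test") {
  d <- pair_differences(pairs, variable, orientation, stratum)
  ba <- bland_altman(pairs, variable, stratum, orientation)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lo, ba$loa_hi),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(
      x = paste0("Mean of methods (", variable, ")"),
      y = paste0("Difference (", orientation_label(orientation), ")"),
      title = sprintf("Bland-Altman: %s, %s (bias %.2f, LoA %.2f to %.2f)",
                      variable, stratum, ba$bias, ba$loa_lo, ba$loa_hi)
    ) +
    ggplot2::theme_minimal()
}

orientation_label <- function(orientation) {
  if (orientation == "ref_minus_test") "reference - test" else "test - reference"
}

#' Half-circle polar plot of trending points
#'
#' Points at (radius, angle from the polar axis), with rays marking the
#' +/- 30 degree concordance band and a dotted arc at the exclusion-zone
#' radius. Excluded points are hollow.
#'
#' @param trend A `coagree_trend` from [trend_analysis()].
#' @param limit_deg Concordance band half-width to draw. Defaults to the
#'   analysis value.
#' @return A ggplot object.
#' @export
plot_polar <- function(trend, limit_deg = trend$summary$limit_deg) {
  pts <- trend$points
  pts$x <- pts$radius * cospi(pts$angle_deg / 180)
  pts$y <- pts$radius * sinpi(pts$angle_deg / 180)
  rmax <- max(pts$radius, trend$summary$exclusion_threshold) * 1.1
  band <- tibble::tibble(
    angle = c(limit_deg, -limit_deg),
    xend = rmax * cospi(c(limit_deg, -limit_deg) / 180),
    yend = rmax * sinpi(c(limit_deg, -limit_deg) / 180)
  )
  arc <- tibble::tibble(theta = seq(-90, 90, by = 2)) |>
    dplyr::mutate(
      x = trend$summary$exclusion_threshold * cospi(.data$theta / 180),
      y = trend$summary$exclusion_threshold * sinpi(.data$theta / 180)
    )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = band,
                          ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                                       yend = .data$yend),
                          linetype = "dashed", colour = "grey40",
                          inherit.aes = FALSE) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = rmax, yend = 0),
                          colour = "grey60", inherit.aes = FALSE) +
    ggplot2::geom_path(data = arc, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = sprintf("Change in %s (polar axis)", trend$variable),
      y = NULL,
      title = sprintf(
        "Polar trending plot: %.1f%% within +/-%g deg (mean deviation %.1f deg)",
        trend$summary$concordance_pct, limit_deg,
        trend$summary$mean_angular_deviation)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.coagree_trend <- function(object, ...) plot_polar(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.coagree_report <- function(object, ...) {
  plot_bland_altman(object$pairs, "ci",
                    orientation = object$provenance$orientation)
}
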