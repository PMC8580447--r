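#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot normalized weekly feature trajectories
#'
#' Line plot of selected z-scored features across the 168 hours of the week,
#' optionally shaded by fitted subdivision.
#'
#' @param scaled Z-scored hourly table (from [zscore_hourly()]).
#' @param features Which features to draw (default: tempo, loudness,
#'   danceability).
#' @param model Optional `subdivision_model` whose labels shade the
#'   background.
#' @return A ggplot object.
#' @export
plot_weekly_features <- function(scaled,
                                 features = c("tempo", "loudness",
                                              "danceability"),
                                 model = NULL) {
  features <- intersect(features, names(scaled))
  long <- tidyr::pivot_longer(scaled[c("hour_of_week", features)],
                              -"hour_of_week", names_to = "feature",
                              values_to = "z")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$hour_of_week, .data$z,
                                          colour = .data$feature))
  if (!is.null(model)) {
    p <- p + ggplot2::geom_tile(
      data = dplyr::mutate(model$labels, z = 0),
      ggplot2::aes(.data$hour_of_week, y = 0, fill = .data$subdivision),
      height = Inf, alpha = 0.15, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(1, 168, 24),
                                labels = c("Mon", "Tue", "Wed", "Thu",
                                           "Fri", "Sat", "Sun")) +
    ggplot2::labs(x = "hour of week", y = "normalized feature value",
                  colour = "feature", fill = "subdivision") +
    ggplot2::theme_minimal()
}

#' Autoplot a subdivision model
#'
#' Heat map of relative centroid profiles: subdivisions against features,
#' red above the weekly grand mean and blue below, each feature scaled by
#' its largest absolute deviation so decibel and BPM features share the
#' palette.
#'
#' @param object A `subdivision_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subdivision_model
#' @export
autoplot.subdivision_model <- function(object, ...) {
  cen <- object$centroids |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(scaled_rel = .data$relative /
                    max(abs(.data$relative), 1e-12)) |>
    dplyr::ungroup()
  ggplot2::ggplot(cen, ggplot2::aes(
    x = factor(.data$subdivision, levels = unique(object$clusters$subdivision)),
    y = .data$feature, fill = .data$scaled_rel)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "relative\nto grand mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot diversity and variability over the day
#'
#' The 24-hour activity-diversity series (optionally smoothed) and the mean
#' audio-feature variability series on standardized scales, for visual
#' comparison of their diurnal shapes.
#'
#' @param diversity Tibble from [activity_diversity()].
#' @param variability Tibble from [feature_variability()].
#' @param window Odd moving-average window for the smoothed diversity line
#'   (`NULL` to skip smoothing).
#' @return A ggplot object.
#' @export
plot_diversity_variability <- function(diversity, variability, window = 3) {
  zz <- function(x) (x - mean(x)) / stats::sd(x)
  d <- tibble::tibble(hour = diversity$hour,
                      series = "activity diversity",
                      value = zz(diversity$diversity))
  v <- tibble::tibble(hour = variability$hour,
                      series = "feature variability",
                      value = zz(variability$variability))
  long <- dplyr::bind_rows(d, v)
  if (!is.null(window)) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      hour = diversity$hour, series = "activity diversity (smoothed)",
      value = zz(moving_average(diversity$diversity, window))))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$hour, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hour of day", y = "standardized value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot preference statistics
#'
#' Mean preference-difference scores with their confidence intervals, per
#' subdivision, against the zero line.
#'
#' @param object A `preference_stats` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot preference_stats
#' @export
autoplot.preference_stats <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$subdivision <- factor(d$subdivision, levels = subdivision_levels())
  ggplot2::ggplot(d, ggplot2::aes(.data$subdivision, .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(x = NULL, y = "mean preference difference") +
    ggplot2::theme_minimal()
}
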