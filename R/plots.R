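#' Plot cell trajectories
#'
#' Draws every track from a common origin (rose plot) or in the field of
#' view, coloured by arrest call.
#'
#' @param spots A spots tibble.
#' @param common_origin Recentre each track at its first point (default
#'   `TRUE`).
#' @inheritParams classify_arrest
#' @return A ggplot object.
#' @export
plot_tracks <- function(spots, common_origin = TRUE,
                        threshold_um = 10, window_s = 300) {
  spots <- validate_spots(spots)
  metrics <- track_metrics(spots, threshold_um = threshold_um,
                           window_s = window_s)
  df <- dplyr::left_join(spots, metrics[, c("track_id", "arrested")],
                         by = "track_id")
  if (common_origin) {
    df <- df |>
      group_by(.data$track_id) |>
      mutate(x_um = .data$x_um - .data$x_um[1],
             y_um = .data$y_um - .data$y_um[1]) |>
      ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   group = .data$track_id,
                                   colour = .data$arrested)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 labels = c(`FALSE` = "migrating",
                                            `TRUE` = "arrested")) +
    ggplot2::labs(x = expression(paste("x (", mu, "m)")),
                  y = expression(paste("y (", mu, "m)")),
                  colour = NULL)
}

#' Plot per-track velocity distributions
#'
#' @param metrics A per-track metrics tibble from [track_metrics()],
#'   optionally with a `condition` column for faceting.
#' @return A ggplot object: boxplot of migrating-track mean velocities.
#' @export
plot_velocities <- function(metrics) {
  df <- metrics[!metrics$arrested & !is.na(metrics$mean_velocity_um_min), ]
  if (!"condition" %in% names(df)) df$condition <- "cohort"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$mean_velocity_um_min)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::labs(x = NULL,
                  y = expression(paste("mean instantaneous velocity (",
                                       mu, "m/min)")))
}
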