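#' Per-step instantaneous speeds of cell tracks
#'
#' Computes the instantaneous speed of every step of every track: the
#' Euclidean distance between consecutive positions divided by the step
#' duration, reported in um/min. Per-step durations are used, so irregular
#' frame intervals are handled correctly.
#'
#' @param spots A spots data frame with columns `track_id`, `time_s`,
#'   `x_um`, `y_um` (the format returned by [read_tracks()] and
#'   [simulate_tracks()]). Positions in um, times in seconds.
#' @return A tibble with one row per step: `track_id`, `step` (1-based index
#'   of the step within its track), `speed_um_min`.
#' @examples
#' spots <- tibble::tibble(track_id = "a", time_s = c(0, 5),
#'                         x_um = c(0, 3), y_um = c(0, 4))
#' instantaneous_speeds(spots) # 5 um in 5 s = 60 um/min
#' @export
instantaneous_speeds <- function(spots) {
  spots <- validate_spots(spots)
  out <- spots |>
    group_by(.data$track_id) |>
    summarise(speed_um_min = list(step_speeds(.data$time_s, .data$x_um, .data$y_um)),
              .groups = "drop")
  tibble(
    track_id = rep(out$track_id, lengths(out$speed_um_min)),
    step = unlist(lapply(lengths(out$speed_um_min), seq_len), use.names = FALSE),
    speed_um_min = unlist(out$speed_um_min, use.names = FALSE)
  )
}

# Vector core: speeds (um/min) for one track given times (s) and positions (um)
step_speeds <- function(time_s, x_um, y_um) {
  if (length(time_s) < 2L) abort("track too short: need at least 2 points for speeds")
  d <- sqrt(diff(x_um)^2 + diff(y_um)^2)
  dt <- diff(time_s)
  60 * d / dt
}

#' Maximum excursion of a track
#'
#' The maximum distance travelled on the substrate, defined as the maximum
#' Euclidean distance separating any two points of the track -- not the net
#' displacement and not the path length. A single-point track has excursion 0.
#'
#' @param x_um,y_um Numeric position vectors (um) of one track.
#' @return Maximum pairwise distance, um.
#' @examples
#' max_excursion(c(0, 3, 0), c(0, 4, 0)) # 5
#' @export
max_excursion <- function(x_um, y_um) {
  if (length(x_um) != length(y_um)) abort("x_um and y_um must have equal length")
  if (length(x_um) == 0L) abort("empty track")
  if (length(x_um) == 1L) return(0)
  max(stats::dist(cbind(x_um, y_um)))
}

#' Classify a track as arrested or migrating
#'
#' A cell is arrested when its maximum excursion over the classification
#' window is strictly below the distance threshold (default 10 um per 5 min,
#' i.e. a rate below 2 um/min). For tracks whose duration differs from the
#' window the threshold scales linearly with duration, preserving the rate
#' criterion. An excursion exactly at the threshold counts as migrating.
#'
#' @param max_excursion_um Maximum excursion of the track, um (vectorised).
#' @param duration_s Track duration, seconds (vectorised).
#' @param threshold_um Distance threshold over the window, um. Default 10.
#' @param window_s Classification window, seconds. Default 300 (5 min).
#' @return Logical: `TRUE` for arrested.
#' @examples
#' classify_arrest(9.9, 300)   # TRUE
#' classify_arrest(10, 300)    # FALSE (boundary is strict)
#' classify_arrest(4.9, 150)   # TRUE (threshold scaled to 5 um)
#' @export
classify_arrest <- function(max_excursion_um, duration_s,
                            threshold_um = 10, window_s = 300) {
  check_number(threshold_um, "threshold_um", min = 0, strict_min = TRUE)
  check_number(window_s, "window_s", min = 0, strict_min = TRUE)
  if (length(max_excursion_um) == 0L) abort("empty track")
  if (any(duration_s <= 0)) abort("duration_s must be positive")
  max_excursion_um < threshold_um * duration_s / window_s
}

#' Per-track migration metrics
#'
#' Computes, for each track, the mean instantaneous velocity, the maximum
#' excursion, the duration, and the arrest call.
#'
#' @inheritParams instantaneous_speeds
#' @inheritParams classify_arrest
#' @return A tibble with one row per track: `track_id`, `n_points`,
#'   `duration_s`, `mean_velocity_um_min`, `max_excursion_um`, `arrested`.
#' @export
track_metrics <- function(spots, threshold_um = 10, window_s = 300) {
  spots <- validate_spots(spots)
  spots |>
    group_by(.data$track_id) |>
    summarise(
      n_points = dplyr::n(),
      duration_s = max(.data$time_s) - min(.data$time_s),
      mean_velocity_um_min = if (dplyr::n() >= 2L)
        mean(step_speeds(.data$time_s, .data$x_um, .data$y_um)) else NA_real_,
      max_excursion_um = max_excursion(.data$x_um, .data$y_um),
      .groups = "drop"
    ) |>
    mutate(arrested = ifelse(
      .data$duration_s > 0,
      classify_arrest(.data$max_excursion_um, .data$duration_s,
                      threshold_um = threshold_um, window_s = window_s),
      TRUE
    ))
}

#' Cohort-level migration summary
#'
#' Aggregates per-track metrics into the statistics used to compare
#' conditions: the percentage of arrested cells and the mean (+/- SEM)
#' instantaneous velocity, computed by default over migrating tracks only
#' (arrested cells sit at near-zero velocity and would otherwise dominate
#' the distribution). Tracks with fewer than `min_points` points are
#' excluded from the velocity statistics (and reported).
#'
#' @param x A spots data frame (columns `track_id`, `time_s`, `x_um`,
#'   `y_um`) or a per-track metrics tibble from [track_metrics()].
#' @inheritParams classify_arrest
#' @param velocity_population `"migrating"` (default) restricts velocity
#'   statistics to migrating tracks; `"all"` uses every track (useful for
#'   deceleration-style analyses).
#' @param min_points Tracks with fewer points are dropped from velocity
#'   statistics. Default 3.
#' @return A one-row tibble: `n_tracks`, `n_arrested`, `percent_arrested`,
#'   `velocity_mean`, `velocity_sem`, `n_velocity_tracks`,
#'   `velocity_defined`, `excursion_mean`, `excursion_sem`,
#'   `excursion_min`, `excursion_max`. Velocity fields are `NA` with
#'   `velocity_defined = FALSE` when no track qualifies.
#' @export
summarize_cohort <- function(x, threshold_um = 10, window_s = 300,
                             velocity_population = c("migrating", "all"),
                             min_points = 3) {
  velocity_population <- match.arg(velocity_population)
  metrics <- if (is_metrics_frame(x)) as_tibble(x) else
    track_metrics(x, threshold_um = threshold_um, window_s = window_s)
  if (nrow(metrics) == 0L) abort("no tracks to summarise")

  short <- metrics$n_points < min_points
  if (any(short)) {
    inform(sprintf("%d track(s) with < %d points excluded from velocity statistics",
                   sum(short), min_points))
  }
  vel_pool <- metrics[!short & !is.na(metrics$mean_velocity_um_min), ]
  if (velocity_population == "migrating") vel_pool <- vel_pool[!vel_pool$arrested, ]

  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  n_vel <- nrow(vel_pool)
  tibble(
    n_tracks = nrow(metrics),
    n_arrested = sum(metrics$arrested),
    percent_arrested = 100 * sum(metrics$arrested) / nrow(metrics),
    velocity_mean = if (n_vel > 0) mean(vel_pool$mean_velocity_um_min) else NA_real_,
    velocity_sem = if (n_vel > 0) sem(vel_pool$mean_velocity_um_min) else NA_real_,
    n_velocity_tracks = n_vel,
    velocity_defined = n_vel > 0,
    excursion_mean = mean(metrics$max_excursion_um),
    excursion_sem = sem(metrics$max_excursion_um),
    excursion_min = min(metrics$max_excursion_um),
    excursion_max = max(metrics$max_excursion_um)
  )
}

is_metrics_frame <- function(x) {
  is.data.frame(x) &&
    all(c("track_id", "n_points", "mean_velocity_um_min",
          "max_excursion_um", "arrested") %in% names(x))
}

# Shared validation for the spots format. Checks required columns, ordering,
# and (by default) uniformity of the frame interval within each track.
validate_spots <- function(spots, check_uniform_dt = TRUE, rel_tol = 1e-6) {
  required <- c("track_id", "time_s", "x_um", "y_um")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0L) {
    abort(sprintf("spots data frame is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(spots) == 0L) abort("spots data frame is empty")
  spots <- as_tibble(spots) |> arrange(.data$track_id, .data$time_s)
  dup <- duplicated(spots[, c("track_id", "time_s")])
  if (any(dup)) abort("duplicate (track_id, time_s) rows in spots data")
  if (check_uniform_dt) {
    bad <- spots |>
      group_by(.data$track_id) |>
      summarise(uneven = {
        dt <- diff(.data$time_s)
        length(dt) > 1L && (max(dt) - min(dt)) > rel_tol * max(dt)
      }, .groups = "drop")
    if (any(bad$uneven)) {
      warn(sprintf("non-uniform frame interval in track(s): %s (per-step durations are used)",
                   paste(utils::head(bad$track_id[bad$uneven], 5), collapse = ", ")))
    }
  }
  spots
}
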