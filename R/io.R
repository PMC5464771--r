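#' Read cell tracks from a tracking-tool spot table
#'
#' Reads the spot-table CSV dialect exported by common particle-tracking
#' tools (header row, comma separator, decimal point; one row per spot).
#' Default column names are `TRACK_ID`, `POSITION_X`, `POSITION_Y` and
#' `POSITION_T` (seconds) or `FRAME` (converted to seconds via `dt_s`).
#' Any z-position column is ignored with a warning: the analysis is 2D.
#'
#' @param path CSV file path.
#' @param col_map Named character vector remapping the expected roles to
#'   the file's column names, e.g.
#'   `c(track_id = "TrackID", x = "x", y = "y", time = "t")`. Recognised
#'   roles: `track_id`, `x`, `y`, `time`, `frame`.
#' @param dt_s Frame interval in seconds, required when only a frame
#'   column is present.
#' @return A spots tibble (`track_id`, `time_s`, `x_um`, `y_um`), sorted
#'   by track and time.
#' @export
read_tracks <- function(path, col_map = NULL, dt_s = NULL) {
  defaults <- c(track_id = "TRACK_ID", x = "POSITION_X", y = "POSITION_Y",
                time = "POSITION_T", frame = "FRAME")
  map <- defaults
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  # the package's own spots dialect round-trips without a column map
  if (is.null(col_map) &&
      all(c("track_id", "time_s", "x_um", "y_um") %in% names(df))) {
    map <- c(track_id = "track_id", x = "x_um", y = "y_um",
             time = "time_s", frame = "FRAME")
  }

  zcols <- grep("^(POSITION_)?Z$", names(df), ignore.case = TRUE, value = TRUE)
  if (length(zcols) > 0L) {
    warn(sprintf("ignoring z column(s) %s: positions are treated as 2D",
                 paste(zcols, collapse = ", ")))
  }

  for (role in c("track_id", "x", "y")) {
    if (!map[[role]] %in% names(df)) {
      abort(sprintf("missing mapped column '%s' (role: %s)", map[[role]], role))
    }
  }
  has_time <- map[["time"]] %in% names(df)
  has_frame <- map[["frame"]] %in% names(df)
  if (has_time) {
    time_s <- as.numeric(df[[map[["time"]]]])
  } else if (has_frame) {
    if (is.null(dt_s)) {
      abort(sprintf("file has a frame column ('%s') but no time column: supply dt_s",
                    map[["frame"]]))
    }
    time_s <- as.numeric(df[[map[["frame"]]]]) * dt_s
  } else {
    abort(sprintf("missing mapped column '%s' (role: time) or '%s' (role: frame)",
                  map[["time"]], map[["frame"]]))
  }

  spots <- tibble(
    track_id = as.character(df[[map[["track_id"]]]]),
    time_s = time_s,
    x_um = as.numeric(df[[map[["x"]]]]),
    y_um = as.numeric(df[[map[["y"]]]])
  )
  validate_spots(spots)
}

#' Read force-indentation curves
#'
#' Auto-detects the curve dialect from the header: raw curves carry columns
#' `D_um`, `d_um` (base and tip displacement); processed curves carry
#' `delta_um`, `F_nN` (indentation depth and force). An optional
#' `curve_id` column separates multiple curves; a file with both dialects'
#' columns is rejected as ambiguous.
#'
#' @param path CSV file path.
#' @return A tibble of class `raw_curves` or `processed_curves` with a
#'   `curve_id` column and the dialect's two measurement columns.
#' @export
read_force_curves <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- all(c("D_um", "d_um") %in% names(df))
  processed <- all(c("delta_um", "F_nN") %in% names(df))
  if (raw && processed) {
    abort("ambiguous header: both raw (D_um, d_um) and processed (delta_um, F_nN) columns present")
  }
  if (!raw && !processed) {
    abort("unrecognised header: expected raw columns (D_um, d_um) or processed columns (delta_um, F_nN)")
  }
  out <- as_tibble(df)
  if (!"curve_id" %in% names(out)) out <- tibble(curve_id = "curve-1", out)
  class(out) <- c(if (raw) "raw_curves" else "processed_curves", class(out))
  out
}

#' Write per-track metrics and cohort summaries
#'
#' `write_track_metrics()` writes the [track_metrics()] tibble as CSV;
#' `write_cohort_summary()` writes the [summarize_cohort()] row as JSON.
#'
#' @param metrics Per-track metrics tibble.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_track_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(metrics)
}

#' @rdname write_track_metrics
#' @param summary Cohort summary tibble.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(as.list(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Read rheometer gap sweeps
#'
#' @param path CSV with columns `sample_id`, `gap_mm`, `G_prime_Pa`.
#' @return A sweep tibble.
#' @export
read_sweeps <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sample_id", "gap_mm", "G_prime_Pa"), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("sweep file is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}
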