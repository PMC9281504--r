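# Delimited-text I/O for wheel time series, per-push metrics and manifests.
#
# On-disk dialect: comma-delimited, one header row, lowercase channel names
# (time, fx, fy, fz, mx, my, mz, theta). Angle on disk is cumulative radians.
# Raw files follow the wheel's own sign convention: on the left wheel,
# forward propulsion is negative theta/mz, so reading with `flip = TRUE`
# (the default for left wheels) normalizes both wheels to
# propulsion-positive.

#' Read one wheel's trial recording
#'
#' Reads a comma-delimited file with the eight channels `time, fx, fy, fz,
#' mx, my, mz, theta` (case-insensitive header), sorts rows by time and
#' validates integrity and sampling.
#'
#' @param path File to read.
#' @param side `"left"` or `"right"` wheel.
#' @param fs Nominal sampling rate in Hz.
#' @param flip Flip the sign of `theta` and `mz` so forward propulsion is
#'   positive. Defaults to `TRUE` for the left wheel, `FALSE` for the right.
#'
#' @return A validated [wheel_ts()] tibble.
#' @export
read_trial <- function(path, side = c("right", "left"), fs = 240,
                       flip = identical(side, "left")) {
  side <- match.arg(side)
  if (!file.exists(path)) {
    abort_pushrim(sprintf("file not found: %s", path), class = "io")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  names(df) <- tolower(names(df))
  missing <- setdiff(CHANNELS, names(df))
  if (length(missing) > 0) {
    abort_pushrim(
      paste0("missing channel: ", paste(missing, collapse = ", ")),
      class = "format"
    )
  }
  if (isTRUE(flip)) {
    df$theta <- -df$theta
    df$mz <- -df$mz
  }
  wheel_ts(df, side = side, fs = fs)
}

#' Write one wheel's trial recording
#'
#' Inverse of [read_trial()]: writes the eight channels as CSV, flipping
#' `theta`/`mz` back to the wheel's raw convention when `flip = TRUE`.
#' Round-trips to well beyond 6 significant digits.
#'
#' @param ts A [wheel_ts()] object.
#' @param path Output file.
#' @param flip Undo the propulsion-positive normalization on write
#'   (default: `TRUE` for left wheels).
#' @return `path`, invisibly.
#' @export
write_trial <- function(ts, path, flip = identical(wheel_side(ts), "left")) {
  df <- as_tibble(ts)[CHANNELS]
  if (isTRUE(flip)) {
    df$theta <- -df$theta
    df$mz <- -df$mz
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write per-push metrics to CSV
#'
#' One row per push; columns `push`, `side`, then the nine parameters
#' `ftot_peak, mz_peak, ror, fef, po_peak, ai, pt, ct, pa`.
#'
#' @param metrics Tibble of per-push metrics as returned by [push_metrics()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0) {
    abort_pushrim("`metrics` must be a non-empty data frame", class = "value")
  }
  cols <- c("push", "side", PARAMETERS)
  missing <- setdiff(cols, names(metrics))
  if (length(missing) > 0) {
    abort_pushrim(
      paste0("metrics are missing columns: ", paste(missing, collapse = ", ")),
      class = "format"
    )
  }
  out <- tryCatch(
    readr::write_csv(as_tibble(metrics)[cols], path, progress = FALSE),
    error = function(e) abort_pushrim(conditionMessage(e), class = "io")
  )
  invisible(path)
}

#' Read per-push metrics written by [write_metrics()]
#'
#' @param path CSV file.
#' @return A tibble with one row per push.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) {
    abort_pushrim(sprintf("file not found: %s", path), class = "io")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a study manifest
#'
#' A manifest is a YAML file listing, for each recorded wheel, the
#' participant, condition (`with_racket` / `without_racket`), wheel side,
#' and file path, plus each participant's dominant side, optional geometry
#' overrides and optional config overrides. See `write_study()` for the
#' layout this package writes.
#'
#' @param path YAML manifest file.
#' @return A list with elements `trials` (tibble: participant, condition,
#'   side, file, flip), `dominant` (named character vector), `geometry`
#'   ([wheel_geometry()]), and `config` (named list of overrides).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_pushrim(sprintf("file not found: %s", path), class = "io")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$trials) || length(raw$trials) == 0) {
    abort_pushrim("manifest lists no trials", class = "format")
  }
  trials <- purrr::map(raw$trials, function(tr) {
    tibble(
      participant = as.character(tr$participant),
      condition = check_choice(tr$condition, "condition",
                               c("with_racket", "without_racket")),
      side = check_choice(tr$side, "side", c("left", "right")),
      file = file.path(dirname(path), tr$file),
      flip = tr$flip %||% identical(tr$side, "left")
    )
  })
  trials <- list_rbind(trials)
  dominant <- purrr::map_chr(raw$participants %||% list(), function(p) {
    check_choice(p$dominant_side, "dominant_side", c("left", "right"))
  })
  geo <- raw$geometry %||% list()
  geometry <- wheel_geometry(
    wheel_radius = geo$wheel_radius %||% 0.3302,
    handrim_radius = geo$handrim_radius %||% 0.267,
    camber = geo$camber %||% 18
  )
  list(trials = trials, dominant = dominant, geometry = geometry,
       config = raw$config %||% list())
}
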