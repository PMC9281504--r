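# Core containers: wheel time series, wheel geometry, trial metadata.
#
# A wheel time series is a tibble with one row per sample and the eight
# SmartWheel-style channels. Sign convention after loading: forward
# propulsion is positive theta and positive mz on BOTH wheels (the left
# wheel is flipped at I/O time), so all downstream metrics are side-agnostic.

CHANNELS <- c("time", "fx", "fy", "fz", "mx", "my", "mz", "theta")
FM_CHANNELS <- c("fx", "fy", "fz", "mx", "my", "mz")

#' Construct a validated wheel time series
#'
#' Bundles the eight synchronized channels recorded by an instrumented
#' wheelchair wheel into a tibble carrying the wheel side and the nominal
#' sampling rate as attributes. Channels: `time` (s, strictly increasing),
#' `fx`, `fy`, `fz` (N), `mx`, `my`, `mz` (N·m) and `theta` (rad, cumulative
#' wheel angle, not wrapped). `fy` is the force applied up/down on the
#' pushrim, `fx` laterally, `fz` out of the wheel plane; only the resultant
#' and `mz` enter the kinetic parameters, so the axis convention is carried,
#' not enforced.
#'
#' @param data Data frame with (at least) the eight channel columns.
#' @param side `"left"` or `"right"`.
#' @param fs Nominal sampling rate in Hz (default 240).
#' @param validate Run integrity checks (default `TRUE`).
#'
#' @return A `pushrim_ts` tibble, rows sorted by time.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 240)
#' ts <- wheel_ts(
#'   data.frame(time = t, fx = 0, fy = 0, fz = 0, mx = 0, my = 0, mz = 0,
#'              theta = 4.24 * t),
#'   side = "right"
#' )
#' wheel_fs(ts)
wheel_ts <- function(data, side = c("right", "left"), fs = 240, validate = TRUE) {
  side <- match.arg(side)
  check_number(fs, "fs", min = 1e-6)
  missing <- setdiff(CHANNELS, names(data))
  if (length(missing) > 0) {
    abort_pushrim(
      paste0("missing channel: ", paste(missing, collapse = ", ")),
      class = "format"
    )
  }
  data <- as_tibble(data)[CHANNELS]
  data <- arrange(data, .data$time)
  out <- new_tibble(data, side = side, fs = fs, class = "pushrim_ts")
  if (validate) validate_wheel_ts(out)
  out
}

#' @rdname wheel_ts
#' @param ts A `pushrim_ts` object.
#' @export
wheel_fs <- function(ts) attr(ts, "fs")

#' @rdname wheel_ts
#' @export
wheel_side <- function(ts) attr(ts, "side")

#' Validate the integrity of a wheel time series
#'
#' Checks that every channel is numeric and free of NA/NaN (values are never
#' interpolated: a silent fill could fabricate pushes), that time is strictly
#' increasing, and that the median inter-sample interval is within 1% of
#' `1 / wheel_fs(ts)`.
#'
#' @param ts A `pushrim_ts` object.
#' @return `ts`, invisibly.
#' @export
validate_wheel_ts <- function(ts) {
  if (nrow(ts) < 2L) {
    abort_pushrim("a wheel time series needs at least 2 samples", class = "format")
  }
  for (ch in CHANNELS) {
    v <- ts[[ch]]
    if (!is.numeric(v)) {
      abort_pushrim(sprintf("channel `%s` is not numeric", ch), class = "format")
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort_pushrim(
        sprintf("channel `%s` has a missing/non-finite value at row %d", ch, bad[1]),
        class = "integrity", row = bad[1], channel = ch
      )
    }
  }
  dt <- diff(ts$time)
  if (any(dt <= 0)) {
    abort_pushrim("`time` must be strictly increasing", class = "integrity")
  }
  fs <- wheel_fs(ts)
  if (abs(median(dt) - 1 / fs) > 0.01 / fs) {
    abort_pushrim(
      sprintf(
        "median sampling interval %.6g s deviates more than 1%% from 1/fs = %.6g s",
        median(dt), 1 / fs
      ),
      class = "sampling"
    )
  }
  invisible(ts)
}

#' Wheel and handrim geometry
#'
#' Defaults describe the 26-inch multi-sport wheel used in court sports:
#' wheel radius 0.3302 m, handrim radius 0.267 m, 18 degrees of camber
#' (informational; camber does not enter any computation).
#'
#' @param wheel_radius Wheel radius in metres.
#' @param handrim_radius Handrim radius in metres; must be smaller than the
#'   wheel radius. Used to convert the propulsive moment into a tangential
#'   force (`ftan = mz / handrim_radius`).
#' @param camber Camber angle in degrees (carried, unused).
#'
#' @return A `pushrim_geometry` list.
#' @export
wheel_geometry <- function(wheel_radius = 0.3302, handrim_radius = 0.267,
                           camber = 18) {
  check_number(wheel_radius, "wheel_radius", min = 1e-6)
  check_number(handrim_radius, "handrim_radius", min = 1e-6)
  check_number(camber, "camber", min = -90, max = 90)
  if (handrim_radius >= wheel_radius) {
    abort_pushrim("handrim_radius must be smaller than wheel_radius", class = "value")
  }
  structure(
    list(wheel_radius = wheel_radius, handrim_radius = handrim_radius,
         camber = camber),
    class = "pushrim_geometry"
  )
}

#' Trial metadata
#'
#' @param participant_id Participant label.
#' @param condition `"with_racket"` or `"without_racket"`.
#' @param dominant_side `"left"` or `"right"` — the hand holding the racket
#'   in the with-racket condition.
#' @param target_speed Paced speed in m/s (default 1.4, i.e. 5 km/h).
#'
#' @return A `pushrim_meta` list.
#' @export
trial_meta <- function(participant_id, condition = c("without_racket", "with_racket"),
                       dominant_side = c("right", "left"), target_speed = 1.4) {
  condition <- match.arg(condition)
  dominant_side <- match.arg(dominant_side)
  check_number(target_speed, "target_speed", min = 0)
  structure(
    list(participant_id = as.character(participant_id), condition = condition,
         dominant_side = dominant_side, target_speed = target_speed),
    class = "pushrim_meta"
  )
}

#' @export
print.pushrim_ts <- function(x, ...) {
  cat(sprintf(
    "<wheel time series: %s wheel, %d samples @ %g Hz, %.2f s>\n",
    wheel_side(x), nrow(x), wheel_fs(x), diff(range(x$time))
  ))
  NextMethod()
}

#' @export
print.pushrim_geometry <- function(x, ...) {
  cat(sprintf(
    "<wheel geometry: wheel r = %.4f m, handrim r = %.4f m, camber %g deg>\n",
    x$wheel_radius, x$handrim_radius, x$camber
  ))
  invisible(x)
}
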