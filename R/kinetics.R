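# The nine per-push outcome parameters.
#
#   ftot_peak  N      peak resultant force, max sqrt(fx^2+fy^2+fz^2)
#   mz_peak    N*m    peak propulsive moment
#   ror        N/s    rate of rise: max in-push d(ftot)/dt
#   fef        %      fraction of effective force, |ftan/ftot| * 100 with
#                     ftan = mz / handrim_radius, time-averaged over the push
#   po_peak    W      peak power, max omega * mz
#   ai         N*m*s  angular impulse, mean(mz) * push time
#   pt         s      push (contact) time
#   ct         s      cycle time, start-to-start (absent for last push)
#   pa         deg    wheel angle traversed during contact

PARAMETERS <- c("ftot_peak", "mz_peak", "ror", "fef", "po_peak", "ai",
                "pt", "ct", "pa")

push_range <- function(push, n) {
  s <- push$start_index
  e <- push$end_index
  if (is.null(s) || is.null(e) || s > e || s < 1 || e > n) {
    abort_pushrim("push interval outside series bounds", class = "value")
  }
  s:e
}

#' Peak total force of a push
#'
#' @param ftot Total-force series (N), see [total_force()].
#' @param push One push: a list or one-row tibble with `start_index` and
#'   `end_index` (1-based, inclusive).
#' @return Maximum of `ftot` over the push, in newtons.
#' @export
ftot_peak <- function(ftot, push) {
  max(ftot[push_range(push, length(ftot))])
}

#' Peak propulsive moment of a push
#'
#' `mz` must be sign-normalized so propulsion is positive (see
#' [read_trial()]). An all-negative (braking) push returns its (negative)
#' maximum and raises a QC warning rather than being dropped.
#'
#' @param mz Propulsive-moment series (N·m).
#' @inheritParams ftot_peak
#' @return Maximum of `mz` over the push, in N·m.
#' @export
mz_peak <- function(mz, push) {
  out <- max(mz[push_range(push, length(mz))])
  if (out < 0) {
    warn_qc(sprintf("push [%d, %d] has negative peak moment (braking?)",
                    push$start_index, push$end_index))
  }
  out
}

#' Rate of rise of the total force
#'
#' Maximum time-derivative of the total force within the push. The
#' derivative is a Savitzky-Golay filter (5 samples, order 2 by default —
#' essentially exact on clean signals) applied over the whole series, so
#' the window sees the true below-threshold samples around the push onset
#' instead of padding. On noisy recordings a short derivative window
#' amplifies sensor noise by about `fs * sqrt(1/10)`, so the pipeline
#' widens it via the `ror_window` config key (default 15). The
#' `"peak_over_time"` variant (peak force divided by time from push start
#' to the peak sample) is available for sensitivity checks.
#'
#' @inheritParams ftot_peak
#' @param fs Sampling rate in Hz.
#' @param window,polyorder Derivative filter parameters (defaults 5, 2).
#' @param variant `"max_derivative"` (default) or `"peak_over_time"`.
#' @return Rate of rise in N/s.
#' @export
rate_of_rise <- function(ftot, push, fs, window = 5, polyorder = 2,
                         variant = c("max_derivative", "peak_over_time")) {
  variant <- match.arg(variant)
  rng <- push_range(push, length(ftot))
  if (length(rng) < 3) {
    abort_pushrim("push too short for a rate of rise (need >= 3 samples)",
                  class = "short_push")
  }
  if (variant == "peak_over_time") {
    ipk <- rng[which.max(ftot[rng])]
    dt <- (ipk - push$start_index) / fs
    if (dt <= 0) dt <- 1 / fs
    return(max(ftot[rng]) / dt)
  }
  w <- min(window, if (is_odd(length(ftot))) length(ftot) else length(ftot) - 1L)
  d <- sg_derivative(ftot, window = w, polyorder = min(polyorder, w - 2L), fs = fs)
  max(d[rng])
}

#' Fraction of effective force
#'
#' The tangential (propelling) force is derived from the propulsive moment
#' as `ftan = mz / handrim_radius`; FEF is the percentage `|ftan / ftot| *
#' 100`, by default time-averaged over the push. Samples where the implied
#' tangential force exceeds the total force (ratio > 100%) raise a QC
#' warning and are never clamped.
#'
#' @inheritParams ftot_peak
#' @param mz Propulsive-moment series (N·m).
#' @param geometry A [wheel_geometry()].
#' @param variant `"time_average"` (default), `"ratio_of_means"` or
#'   `"at_peak"`.
#' @return FEF in percent (nominally 0-100).
#' @export
fef <- function(ftot, mz, push, geometry = wheel_geometry(),
                variant = c("time_average", "ratio_of_means", "at_peak")) {
  variant <- match.arg(variant)
  rng <- push_range(push, length(ftot))
  f <- ftot[rng]
  if (any(f == 0)) {
    abort_pushrim("push contains samples with zero total force", class = "degenerate_push")
  }
  ftan <- mz[rng] / geometry$handrim_radius
  ratio <- abs(ftan / f)
  if (any(ratio > 1 + 1e-12)) {
    warn_qc(sprintf(
      "%d sample(s) in push [%d, %d] imply tangential force above total force",
      sum(ratio > 1 + 1e-12), push$start_index, push$end_index
    ))
  }
  100 * switch(variant,
    time_average = mean(ratio),
    ratio_of_means = abs(mean(ftan)) / mean(f),
    at_peak = ratio[which.max(f)]
  )
}

#' Peak power output of a push
#'
#' Maximum of the instantaneous handrim power `omega * mz` over the push,
#' with `omega` the wheel angular velocity (rad/s) from
#' [angular_velocity()].
#'
#' @param omega Angular-velocity series (rad/s).
#' @param mz Propulsive-moment series (N·m).
#' @inheritParams ftot_peak
#' @return Peak power in watts.
#' @export
po_peak <- function(omega, mz, push) {
  rng <- push_range(push, length(mz))
  if (length(omega) != length(mz)) {
    abort_pushrim("`omega` and `mz` must have the same length", class = "value")
  }
  max(omega[rng] * mz[rng])
}

#' Angular impulse of a push
#'
#' Mean propulsive moment over the push times the push time — the discrete
#' time integral of `mz` over the contact interval.
#'
#' @param mz Propulsive-moment series (N·m).
#' @inheritParams ftot_peak
#' @param fs Sampling rate in Hz.
#' @return Angular impulse in N·m·s.
#' @export
angular_impulse <- function(mz, push, fs) {
  rng <- push_range(push, length(mz))
  mean(mz[rng]) * length(rng) / fs
}

#' Push (contact) time
#'
#' `(end_index - start_index + 1) / fs`: both boundary samples are at or
#' above the detection threshold and the interval is treated inclusively.
#'
#' @inheritParams angular_impulse
#' @return Push time in seconds.
#' @export
push_time <- function(push, fs) {
  if (push$start_index > push$end_index) {
    abort_pushrim("push has start_index > end_index", class = "value")
  }
  (push$end_index - push$start_index + 1) / fs
}

#' Cycle time between two consecutive pushes
#'
#' Start-to-start interval `(start_index(next) - start_index(push)) / fs`.
#' Undefined (and not computed) for the last analyzed push.
#'
#' @param push,push_next Consecutive pushes (`push_next` strictly after).
#' @param fs Sampling rate in Hz.
#' @return Cycle time in seconds.
#' @export
cycle_time <- function(push, push_next, fs) {
  if (push_next$start_index <= push$end_index) {
    abort_pushrim("pushes overlap or are out of order", class = "order")
  }
  (push_next$start_index - push$start_index) / fs
}

#' Push angle
#'
#' Wheel rotation traversed during contact, `(theta[end] - theta[start])`
#' in degrees. `theta` must be cumulative (unwrapped). A negative angle
#' (backward motion during contact) raises a QC warning.
#'
#' @param theta Cumulative wheel angle (rad).
#' @inheritParams ftot_peak
#' @return Push angle in degrees.
#' @export
push_angle <- function(theta, push) {
  rng <- push_range(push, length(theta))
  out <- (theta[push$end_index] - theta[push$start_index]) * 180 / pi
  if (out < 0) {
    warn_qc(sprintf("push [%d, %d] has negative push angle (backward motion)",
                    push$start_index, push$end_index))
  }
  out
}

#' Compute all nine parameters for every analyzed push
#'
#' @param ts Preprocessed [wheel_ts()] (offset-corrected, smoothed).
#' @param pushes A `pushrim_pushes` tibble after [exclude_transitional()].
#' @param omega Angular-velocity series from [angular_velocity()].
#' @param geometry A [wheel_geometry()].
#' @param config A [pushrim_config()].
#' @return Tibble with one row per analyzed push: `push`, `side`, and the
#'   nine parameter columns (`ct` is `NA` for the last analyzed push).
#' @export
push_metrics <- function(ts, pushes, omega, geometry = wheel_geometry(),
                         config = pushrim_config()) {
  if (!isTRUE(attr(pushes, "excluded"))) {
    abort_pushrim("apply exclude_transitional() before computing metrics",
                  class = "value")
  }
  sel <- filter(as_tibble(pushes), .data$analyzed)
  if (nrow(sel) == 0) {
    abort_pushrim("no analyzed pushes", class = "insufficient_pushes")
  }
  fs <- wheel_fs(ts)
  ftot <- total_force(ts)
  rows <- purrr::map(seq_len(nrow(sel)), function(i) {
    p <- sel[i, ]
    ct <- if (i < nrow(sel)) cycle_time(p, sel[i + 1, ], fs) else NA_real_
    tibble(
      push = p$push,
      side = wheel_side(ts),
      ftot_peak = ftot_peak(ftot, p),
      mz_peak = mz_peak(ts$mz, p),
      ror = rate_of_rise(ftot, p, fs, window = config$ror_window,
                         polyorder = config$ror_polyorder,
                         variant = config$ror_variant),
      fef = fef(ftot, ts$mz, p, geometry, variant = config$fef_variant),
      po_peak = po_peak(omega, ts$mz, p),
      ai = angular_impulse(ts$mz, p, fs),
      pt = push_time(p, fs),
      ct = ct,
      pa = push_angle(ts$theta, p)
    )
  })
  list_rbind(rows)
}

#' Summarize per-push metrics into a trial summary
#'
#' Arithmetic mean of each parameter over the analyzed pushes (cycle time
#' over the pushes where it is defined), plus the mean linear wheel
#' velocity over the trial.
#'
#' @param metrics Per-push metrics from [push_metrics()].
#' @param velocity Velocity tibble from [preprocess_trial()] (column `v`),
#'   or a numeric velocity series.
#' @return One-row tibble: `side`, `n_analyzed`, `velocity`, and the nine
#'   parameter means.
#' @export
summarize_trial <- function(metrics, velocity) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0) {
    abort_pushrim("no analyzed pushes to summarize", class = "insufficient_pushes")
  }
  v <- if (is.data.frame(velocity)) velocity$v else velocity
  out <- metrics |>
    group_by(.data$side) |>
    summarise(
      n_analyzed = dplyr::n(),
      across(all_of(PARAMETERS), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  out$ct[is.nan(out$ct)] <- NA_real_
  mutate(out, velocity = mean(v), .after = "n_analyzed")
}
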