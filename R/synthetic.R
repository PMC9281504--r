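# Synthetic instrumented-wheel trials with closed-form ground truth.
#
# Pushes are half-sine force pulses: ftot(t) = F * sin(pi * (t - t0) / PT)
# inside each push, 0 between pushes. The propulsive moment is a fixed
# tangential fraction of the total force times the handrim radius, so
# every outcome parameter has a closed form:
#
#   ftot_peak = F                  ror     = pi * F / PT
#   mz_peak   = tf * F * r         fef     = 100 * tf
#   po_peak   = omega * tf * F * r ai      = (2/pi) * F * tf * r * PT
#   pt        = PT                 ct      = CT
#   pa        = omega * PT * 180/pi
#
# A 30 N detection threshold measures slightly different quantities (it
# trims the sub-threshold tails of each half-sine), so the ground truth
# carries both the nominal forms above and the threshold-consistent
# "observed" forms (columns suffixed `_obs`) that a thresholding pipeline
# should recover exactly in the noise-free limit.

#' Push profile for the synthetic generator
#'
#' Defaults emulate paced (1.4 m/s) propulsion in a multi-sport wheelchair:
#' peak total force 100 N, tangential fraction 0.35 (FEF 35%), push time
#' 0.35 s, cycle time 1.2 s.
#'
#' @param peak_force Peak total force per push, N (> 30 so pushes are
#'   detectable).
#' @param tangential_fraction Fraction of the total force that propels the
#'   wheel, in (0, 1].
#' @param push_duration Push (contact) time, s.
#' @param cycle_duration Start-to-start cycle time, s (> push_duration).
#' @param mean_speed Wheelchair speed, m/s.
#' @return A `pushrim_profile` list.
#' @export
push_profile <- function(peak_force = 100, tangential_fraction = 0.35,
                         push_duration = 0.35, cycle_duration = 1.2,
                         mean_speed = 1.4) {
  check_number(peak_force, "peak_force", min = 30 + 1e-9)
  check_number(tangential_fraction, "tangential_fraction", min = 1e-9, max = 1)
  check_number(push_duration, "push_duration", min = 1e-3)
  check_number(cycle_duration, "cycle_duration", min = 1e-3)
  check_number(mean_speed, "mean_speed", min = 0)
  if (push_duration >= cycle_duration) {
    abort_pushrim("push_duration must be smaller than cycle_duration",
                  class = "validation")
  }
  structure(
    list(peak_force = peak_force, tangential_fraction = tangential_fraction,
         push_duration = push_duration, cycle_duration = cycle_duration,
         mean_speed = mean_speed),
    class = "pushrim_profile"
  )
}

PROFILE_FIELDS <- c("peak_force", "tangential_fraction", "push_duration",
                    "cycle_duration")

#' Recipe for one synthetic trial
#'
#' @param n_pushes Number of generated pushes (>= 4, so at least one
#'   survives transitional exclusion).
#' @param profile A [push_profile()].
#' @param variability Named lognormal SDs (log scale) for the per-push
#'   variation of the profile fields; default 0.05 for all four.
#' @param noise_sd Additive Gaussian sensor noise on the force channels, N
#'   (default 2).
#' @param moment_noise_sd Sensor noise on the moment channels, N·m
#'   (default 0.2, typical of commercial instrumented wheels).
#' @param offsets Optional [channel_offsets()] injected into the signals
#'   (constant + first harmonic in the wheel angle).
#' @param geometry A [wheel_geometry()].
#' @param fs Sampling rate, Hz (default 240).
#' @param seed Integer seed; the same recipe always yields bitwise
#'   identical signals.
#' @param side Wheel side label for the generated series.
#' @param speed_ripple Relative amplitude of an in-push wheel-speed ripple
#'   (default 0: constant speed, which paced straight-line propulsion
#'   approximates well).
#' @param lead_s Coast time before the first and after the last push, s.
#' @param threshold Detection threshold used for the `_obs` ground-truth
#'   columns (default 30 N).
#' @return A `pushrim_recipe` list.
#' @export
trial_recipe <- function(n_pushes = 8, profile = push_profile(),
                         variability = c(peak_force = 0.05,
                                         tangential_fraction = 0.05,
                                         push_duration = 0.05,
                                         cycle_duration = 0.05),
                         noise_sd = 2, moment_noise_sd = 0.2, offsets = NULL,
                         geometry = wheel_geometry(), fs = 240, seed = 1,
                         side = "right", speed_ripple = 0, lead_s = 1,
                         threshold = 30) {
  check_number(n_pushes, "n_pushes", min = 4)
  if (!inherits(profile, "pushrim_profile")) {
    abort_pushrim("`profile` must come from push_profile()", class = "validation")
  }
  vab <- setNames(numeric(length(PROFILE_FIELDS)), PROFILE_FIELDS)
  vab[names(variability)] <- variability
  if (any(vab < 0)) {
    abort_pushrim("variability SDs must be >= 0", class = "validation")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(moment_noise_sd, "moment_noise_sd", min = 0)
  check_number(fs, "fs", min = 1)
  check_number(seed, "seed")
  check_number(speed_ripple, "speed_ripple", min = 0, max = 0.5)
  check_number(lead_s, "lead_s", min = 0.5)
  if (!is.null(offsets) && !inherits(offsets, "pushrim_offsets")) {
    abort_pushrim("`offsets` must come from channel_offsets()", class = "validation")
  }
  structure(
    list(n_pushes = as.integer(n_pushes), profile = profile, variability = vab,
         noise_sd = noise_sd, moment_noise_sd = moment_noise_sd,
         offsets = offsets, geometry = geometry, fs = fs,
         seed = as.integer(seed), side = side, speed_ripple = speed_ripple,
         lead_s = lead_s, threshold = threshold),
    class = "pushrim_recipe"
  )
}

# Per-push parameter draws (lognormal around the profile). This is the
# first RNG consumer under the recipe seed, so summary-level and
# signal-level generation see identical push parameters.
draw_pushes <- function(recipe) {
  pr <- recipe$profile
  v <- recipe$variability
  n <- recipe$n_pushes
  draw <- function(field) {
    pr[[field]] * exp(stats::rnorm(n, 0, v[[field]]))
  }
  peak <- draw("peak_force")
  tf <- pmin(draw("tangential_fraction"), 1)
  pt <- draw("push_duration")
  ct <- draw("cycle_duration")
  pt <- pmin(pt, 0.9 * ct)  # keep contact strictly inside the cycle
  t0 <- recipe$lead_s + c(0, cumsum(ct[-n]))
  new_tibble(list(push = seq_len(n), peak_force = peak,
                  tangential_fraction = tf, push_duration = pt,
                  cycle_duration = ct, t0 = t0), nrow = n)
}

# Continuous-time closed forms, including the threshold-consistent
# "observed" versions (see header comment). Exact for zero speed ripple.
push_truth <- function(pushes, recipe) {
  r <- recipe$geometry$handrim_radius
  omega <- recipe$profile$mean_speed / recipe$geometry$wheel_radius
  thr <- recipe$threshold
  F <- pushes$peak_force
  tf <- pushes$tangential_fraction
  pt <- pushes$push_duration
  ct <- pushes$cycle_duration
  if (any(F <= thr)) {
    abort_pushrim("peak force at or below the detection threshold", class = "validation")
  }
  tq <- (pt / pi) * asin(thr / F)        # sub-threshold tail on each side
  cosq <- sqrt(1 - (thr / F)^2)
  pt_obs <- pt - 2 * tq
  n <- nrow(pushes)
  ct_obs <- c(ct[-n] + tq[-1] - tq[-n], NA_real_)
  new_tibble(list(
    push = pushes$push,
    ftot_peak = F,
    mz_peak = tf * F * r,
    ror = pi * F / pt,
    fef = 100 * tf,
    po_peak = omega * tf * F * r,
    ai = (2 / pi) * F * tf * r * pt,
    pt = pt,
    ct = c(ct[-n], NA_real_),
    pa = omega * pt * 180 / pi,
    ror_obs = pi * F / pt * cosq,
    ai_obs = tf * F * r * (2 * pt / pi) * cosq,
    pt_obs = pt_obs,
    ct_obs = ct_obs,
    pa_obs = omega * pt_obs * 180 / pi
  ), nrow = n)
}

#' Generate one synthetic wheel trial with ground truth
#'
#' Synthesizes the eight channels on a regular time grid: half-sine total
#' force per push, moment channel `mz = tf * ftot * handrim_radius`, the
#' non-tangential force magnitude split 80/20 (by squared magnitude)
#' between the in-plane radial and out-of-plane components, in-plane force
#' rotated with the wheel angle, angle integrating a constant (optionally
#' rippled) angular velocity, then additive Gaussian sensor noise and any
#' injected angle-dependent offsets. Deterministic given the recipe seed.
#'
#' @param recipe A [trial_recipe()].
#' @return A list: `ts` ([wheel_ts()]), `truth` (per-push ground-truth
#'   tibble: nominal closed forms, `_obs` threshold-consistent forms, and
#'   the exact `start_index`/`end_index` a noise-free 30 N segmentation
#'   yields), `pushes` (drawn per-push parameters), `recipe`.
#' @export
generate_trial <- function(recipe) {
  if (!inherits(recipe, "pushrim_recipe")) {
    abort_pushrim("`recipe` must come from trial_recipe()", class = "validation")
  }
  withr::with_seed(recipe$seed, {
    pushes <- draw_pushes(recipe)
    fs <- recipe$fs
    n <- recipe$n_pushes
    t_end <- pushes$t0[n] + pushes$push_duration[n] + recipe$lead_s
    t <- seq(0, t_end, by = 1 / fs)
    N <- length(t)

    geom <- recipe$geometry
    omega_bar <- recipe$profile$mean_speed / geom$wheel_radius
    a <- recipe$speed_ripple

    ftot <- numeric(N)
    mz <- numeric(N)
    theta <- omega_bar * t
    for (i in seq_len(n)) {
      t0 <- pushes$t0[i]; pt <- pushes$push_duration[i]
      inp <- which(t > t0 & t < t0 + pt)
      phase <- pi * (t[inp] - t0) / pt
      f <- pushes$peak_force[i] * sin(phase)
      ftot[inp] <- f
      mz[inp] <- pushes$tangential_fraction[i] * f * geom$handrim_radius
      if (a > 0) {
        # ripple integral: omega_bar * a * (pt/pi) * (1 - cos(phase))
        add <- omega_bar * a * (pt / pi) * (1 - cos(phase))
        theta[inp] <- theta[inp] + add
        post <- t >= t0 + pt
        theta[post] <- theta[post] + omega_bar * a * (2 * pt / pi)
      }
    }

    # force decomposition: tangential + 80/20 (variance) radial/out-of-plane
    tf_s <- numeric(N)
    for (i in seq_len(n)) {
      inp <- which(t > pushes$t0[i] & t < pushes$t0[i] + pushes$push_duration[i])
      tf_s[inp] <- pushes$tangential_fraction[i]
    }
    f_nt <- ftot * sqrt(pmax(0, 1 - tf_s^2))
    fz <- sqrt(0.2) * f_nt
    f_inplane <- sqrt(pmax(0, ftot^2 - fz^2))
    fx <- f_inplane * cos(theta)
    fy <- f_inplane * sin(theta)

    # exact indices a noise-free threshold segmentation produces
    thr <- recipe$threshold
    idx <- purrr::map(seq_len(n), function(i) {
      win <- which(t > pushes$t0[i] & t < pushes$t0[i] + pushes$push_duration[i])
      hit <- win[ftot[win] >= thr]
      c(start = hit[1], end = hit[length(hit)])
    })
    truth <- push_truth(pushes, recipe)
    truth$start_index <- purrr::map_int(idx, ~ as.integer(.x["start"]))
    truth$end_index <- purrr::map_int(idx, ~ as.integer(.x["end"]))
    # discrete (sample-exact) observed values
    truth$pt_obs <- (truth$end_index - truth$start_index + 1) / fs
    truth$ct_obs <- c(diff(truth$start_index) / fs, NA_real_)
    truth$pa_obs <- (theta[truth$end_index] - theta[truth$start_index]) * 180 / pi
    truth$ai_obs <- purrr::map_dbl(seq_len(n), function(i) {
      sum(mz[truth$start_index[i]:truth$end_index[i]]) / fs
    })

    noise <- function(sd) if (sd > 0) stats::rnorm(N, 0, sd) else numeric(N)
    df <- tibble(
      time = t,
      fx = fx + noise(recipe$noise_sd),
      fy = fy + noise(recipe$noise_sd),
      fz = fz + noise(recipe$noise_sd),
      mx = noise(recipe$moment_noise_sd),
      my = noise(recipe$moment_noise_sd),
      mz = mz + noise(recipe$moment_noise_sd),
      theta = theta
    )
    if (!is.null(recipe$offsets)) {
      off <- recipe$offsets
      s <- sin(theta); co <- cos(theta)
      for (i in seq_len(nrow(off))) {
        ch <- off$channel[i]
        df[[ch]] <- df[[ch]] + off$c0[i] + off$a[i] * s + off$b[i] * co
      }
    }
    ts <- wheel_ts(df, side = recipe$side, fs = fs)
    list(ts = ts, truth = truth, pushes = pushes, recipe = recipe)
  })
}

#' Analytic trial summary from a recipe (no signal synthesis)
#'
#' Draws the same per-push parameters as [generate_trial()] (identical RNG
#' path) and averages the threshold-consistent closed forms over the
#' analyzed pushes (first two and last excluded). Useful for large
#' simulation studies where synthesizing and re-analyzing signals would
#' add nothing but runtime; signal-to-summary fidelity is validated
#' separately by the parameter-recovery tests.
#'
#' @param recipe A [trial_recipe()].
#' @return One-row tibble: `n_analyzed`, `velocity`, and the nine
#'   parameter means.
#' @export
trial_truth_summary <- function(recipe) {
  pushes <- withr::with_seed(recipe$seed, draw_pushes(recipe))
  truth <- push_truth(pushes, recipe)
  keep <- 3:(nrow(truth) - 1)
  # the pipeline's cycle time is undefined for the last analyzed push
  ct_obs <- truth$ct_obs[keep]
  ct_obs[length(ct_obs)] <- NA_real_
  m <- function(col) mean(truth[[col]][keep])
  new_tibble(list(
    n_analyzed = length(keep),
    velocity = recipe$profile$mean_speed,
    ftot_peak = m("ftot_peak"),
    mz_peak = m("mz_peak"),
    ror = m("ror_obs"),
    fef = m("fef"),
    po_peak = m("po_peak"),
    ai = m("ai_obs"),
    pt = m("pt_obs"),
    ct = mean(ct_obs, na.rm = TRUE),
    pa = m("pa_obs")
  ), nrow = 1)
}
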