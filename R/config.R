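#' Analysis configuration
#'
#' Every tunable threshold and window of the pipeline in one place, with
#' the defaults used throughout.
#'
#' @param threshold_n Push-detection threshold on the total force, newtons
#'   (default 30). Applied to the offset-corrected total force.
#' @param min_push_s Minimum push duration in seconds (default 0.10); runs
#'   shorter than this after gap-merging are discarded as chatter.
#' @param min_gap_s Below-threshold gaps shorter than this (seconds,
#'   default 0.05) are merged into the surrounding push.
#' @param sg_window,sg_polyorder Savitzky-Golay derivative filter for the
#'   wheel angle (defaults 131 samples, order 1).
#' @param smooth_window,smooth_polyorder Savitzky-Golay smoothing of the
#'   force/moment channels (defaults 15 samples, order 2); `smooth_window
#'   = 0` disables smoothing.
#' @param ror_window,ror_polyorder Savitzky-Golay derivative used for the
#'   rate of rise (defaults 15 samples, order 2).
#' @param ror_variant `"max_derivative"` (default): RoR is the maximum
#'   in-push derivative of the total force; `"peak_over_time"`: peak force
#'   divided by time from push start to the peak.
#' @param fef_variant How the fraction of effective force summarizes a
#'   push: `"time_average"` (default, mean of the instantaneous
#'   `|ftan/ftot|`), `"ratio_of_means"`, or `"at_peak"` (value at the total
#'   force peak).
#' @param d_variant Cohen's d denominator: `"pooled"` (default,
#'   `sqrt((s0^2 + s1^2)/2)`) or `"reference"` (SD of the reference group).
#' @param offset_model `"harmonic"` (default), `"constant"`, or `"none"`.
#' @param bonferroni_m Family size for the Bonferroni adjustment of the
#'   paired contrasts (default 4, the number of simple-effect cell
#'   contrasts in a 2x2 design).
#' @param target_speed,pace_tolerance Paced speed (m/s) and allowed
#'   deviation for [verify_pace()] (defaults 1.4 and 0.1).
#'
#' @return A named list of class `pushrim_config`.
#' @export
pushrim_config <- function(threshold_n = 30,
                           min_push_s = 0.10,
                           min_gap_s = 0.05,
                           sg_window = 131,
                           sg_polyorder = 1,
                           smooth_window = 15,
                           smooth_polyorder = 2,
                           ror_window = 15,
                           ror_polyorder = 2,
                           ror_variant = c("max_derivative", "peak_over_time"),
                           fef_variant = c("time_average", "ratio_of_means", "at_peak"),
                           d_variant = c("pooled", "reference"),
                           offset_model = c("harmonic", "constant", "none"),
                           bonferroni_m = 4,
                           target_speed = 1.4,
                           pace_tolerance = 0.1) {
  check_number(threshold_n, "threshold_n", min = 0)
  check_number(min_push_s, "min_push_s", min = 0)
  check_number(min_gap_s, "min_gap_s", min = 0)
  check_number(bonferroni_m, "bonferroni_m", min = 1)
  structure(list(
    threshold_n = threshold_n, min_push_s = min_push_s, min_gap_s = min_gap_s,
    sg_window = sg_window, sg_polyorder = sg_polyorder,
    smooth_window = smooth_window, smooth_polyorder = smooth_polyorder,
    ror_window = ror_window, ror_polyorder = ror_polyorder,
    ror_variant = match.arg(ror_variant),
    fef_variant = match.arg(fef_variant),
    d_variant = match.arg(d_variant),
    offset_model = match.arg(offset_model),
    bonferroni_m = bonferroni_m,
    target_speed = target_speed, pace_tolerance = pace_tolerance
  ), class = "pushrim_config")
}

# merge named overrides (e.g. from a manifest) into a config
update_config <- function(config, overrides) {
  if (length(overrides) == 0) return(config)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad) > 0) {
    abort_pushrim(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
                  class = "value")
  }
  args <- utils::modifyList(unclass(config), overrides)
  do.call(pushrim_config, args)
}
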