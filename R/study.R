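# 2x2 study generator: n participants x (with/without racket) x
# (dominant/non-dominant hand), with lognormal between-subject variation
# and multiplicative cell effects on the push-profile fields.

STUDY_CONDITIONS <- c("with_racket", "without_racket")
STUDY_SIDES <- c("dominant", "nondominant")

#' Multiplicative 2x2 cell effects on the push profile
#'
#' Each profile field gets a triple `(condition, side, interaction)` of
#' multipliers applied as `base * condition^[with racket] * side^[dominant]
#' * interaction^[with racket & dominant]`. The all-ones default is a null
#' study.
#'
#' @param peak_force,tangential_fraction,push_duration,cycle_duration
#'   Length-3 numeric vectors named `condition`, `side`, `interaction`.
#' @return A `pushrim_effects` list.
#' @export
study_effects <- function(peak_force = c(condition = 1, side = 1, interaction = 1),
                          tangential_fraction = c(condition = 1, side = 1, interaction = 1),
                          push_duration = c(condition = 1, side = 1, interaction = 1),
                          cycle_duration = c(condition = 1, side = 1, interaction = 1)) {
  eff <- list(peak_force = peak_force, tangential_fraction = tangential_fraction,
              push_duration = push_duration, cycle_duration = cycle_duration)
  for (f in names(eff)) {
    v <- eff[[f]]
    if (length(v) != 3 || !all(c("condition", "side", "interaction") %in% names(v)) ||
        any(v <= 0)) {
      abort_pushrim(sprintf(
        "`%s` must be a positive vector with names condition, side, interaction", f
      ), class = "validation")
    }
  }
  structure(eff, class = "pushrim_effects")
}

#' Cell effects emulating racket-sport propulsion asymmetry
#'
#' Multipliers derived from published group means for propulsion with and
#' without a badminton racket: the racket-bearing dominant hand pushes
#' harder (higher peak force, hence rate of rise) but less effectively
#' (lower tangential fraction), pushes shorten slightly and the cycle
#' quickens with the racket.
#'
#' @return A `pushrim_effects` list.
#' @export
racket_effects <- function() {
  study_effects(
    peak_force = c(condition = 1.173, side = 1.173, interaction = 1.160),
    tangential_fraction = c(condition = 0.993, side = 0.871, interaction = 0.825),
    push_duration = c(condition = 0.946, side = 1.0, interaction = 1.0),
    cycle_duration = c(condition = 0.875, side = 1.0, interaction = 1.0)
  )
}

cell_multiplier <- function(effects, field, condition, side) {
  v <- effects[[field]]
  w <- condition == "with_racket"
  d <- side == "dominant"
  unname(v["condition"]^w * v["side"]^d * v["interaction"]^(w & d))
}

#' Generate a synthetic 2x2 propulsion study
#'
#' Per participant, lognormal random effects scale the push-profile fields
#' (between-subject variation); per cell, the multiplicative
#' [study_effects()] are applied on top; each of the four trials gets its
#' own derived seed. The returned design is purely parametric — use
#' [study_summaries()] for analytic per-trial summaries, or
#' [write_study()] / [run_study()] to materialize and re-analyze full
#' signals.
#'
#' @param n_participants Number of participants (>= 2; default 16).
#' @param effects A [study_effects()] (default: null study).
#' @param base_recipe A [trial_recipe()] shared by all trials (its seed is
#'   ignored; per-trial seeds are derived from `seed`).
#' @param between_sd Named lognormal SDs (log scale) of the participant
#'   random effects; default 0.25 for peak force, 0.12 for the tangential
#'   fraction, 0.08 for the durations.
#' @param seed Integer master seed.
#' @return A `pushrim_study` list with elements `design` (tibble:
#'   `participant`, `condition`, `side`, profile fields, `seed_trial`,
#'   nested `recipe`), `effects`, `base_recipe`, `seed`.
#' @export
generate_study <- function(n_participants = 16, effects = study_effects(),
                           base_recipe = trial_recipe(),
                           between_sd = c(peak_force = 0.25,
                                          tangential_fraction = 0.12,
                                          push_duration = 0.08,
                                          cycle_duration = 0.08),
                           seed = 1) {
  check_number(n_participants, "n_participants", min = 2)
  if (!inherits(effects, "pushrim_effects")) {
    abort_pushrim("`effects` must come from study_effects()", class = "validation")
  }
  bsd <- setNames(numeric(length(PROFILE_FIELDS)), PROFILE_FIELDS)
  bsd[names(between_sd)] <- between_sd
  n <- as.integer(n_participants)
  ids <- sprintf("P%02d", seq_len(n))
  withr::with_seed(as.integer(seed), {
    subj <- purrr::map(PROFILE_FIELDS, ~ exp(stats::rnorm(n, 0, bsd[[.x]])))
    names(subj) <- PROFILE_FIELDS
    seeds <- sample.int(2147483646L, n * 4L)
  })
  grid <- tidyr::expand_grid(
    participant = ids,
    condition = STUDY_CONDITIONS,
    side = STUDY_SIDES
  )
  base <- base_recipe$profile
  design <- grid |>
    mutate(
      seed_trial = seeds[row_number()],
      peak_force = base$peak_force *
        subj$peak_force[match(.data$participant, ids)] *
        purrr::map2_dbl(.data$condition, .data$side,
                        ~ cell_multiplier(effects, "peak_force", .x, .y)),
      tangential_fraction = pmin(0.99, base$tangential_fraction *
        subj$tangential_fraction[match(.data$participant, ids)] *
        purrr::map2_dbl(.data$condition, .data$side,
                        ~ cell_multiplier(effects, "tangential_fraction", .x, .y))),
      push_duration = base$push_duration *
        subj$push_duration[match(.data$participant, ids)] *
        purrr::map2_dbl(.data$condition, .data$side,
                        ~ cell_multiplier(effects, "push_duration", .x, .y)),
      cycle_duration = base$cycle_duration *
        subj$cycle_duration[match(.data$participant, ids)] *
        purrr::map2_dbl(.data$condition, .data$side,
                        ~ cell_multiplier(effects, "cycle_duration", .x, .y))
    ) |>
    mutate(push_duration = pmin(.data$push_duration, 0.9 * .data$cycle_duration))
  design$recipe <- purrr::pmap(design, function(participant, condition, side,
                                                seed_trial, peak_force,
                                                tangential_fraction,
                                                push_duration, cycle_duration, ...) {
    trial_recipe(
      n_pushes = base_recipe$n_pushes,
      profile = push_profile(
        peak_force = peak_force, tangential_fraction = tangential_fraction,
        push_duration = push_duration, cycle_duration = cycle_duration,
        mean_speed = base$mean_speed
      ),
      variability = base_recipe$variability,
      noise_sd = base_recipe$noise_sd,
      moment_noise_sd = base_recipe$moment_noise_sd,
      offsets = base_recipe$offsets,
      geometry = base_recipe$geometry,
      fs = base_recipe$fs,
      seed = seed_trial,
      side = if (side == "dominant") "right" else "left",
      speed_ripple = base_recipe$speed_ripple,
      lead_s = base_recipe$lead_s,
      threshold = base_recipe$threshold
    )
  })
  structure(
    list(design = design, effects = effects, base_recipe = base_recipe,
         n_participants = n, seed = as.integer(seed)),
    class = "pushrim_study"
  )
}

#' Analytic per-trial summaries for a generated study
#'
#' Applies [trial_truth_summary()] to every trial of the design: the same
#' per-push draws the signal synthesizer would use, averaged through the
#' threshold-consistent closed forms, without synthesizing any signal.
#'
#' @param study A `pushrim_study` from [generate_study()].
#' @return Tibble: `participant`, `condition`, `side` (dominant /
#'   nondominant), `n_analyzed`, `velocity`, and the nine parameters.
#' @export
study_summaries <- function(study) {
  if (!inherits(study, "pushrim_study")) {
    abort_pushrim("`study` must come from generate_study()", class = "validation")
  }
  sums <- purrr::map(study$design$recipe, trial_truth_summary) |> list_rbind()
  dplyr::bind_cols(
    study$design[c("participant", "condition", "side")],
    sums
  )
}

#' Write a generated study to disk
#'
#' Materializes every trial with [generate_trial()], writes one CSV per
#' wheel recording (raw sign convention: left wheels are flipped on disk),
#' a YAML manifest, and the per-push ground truth.
#'
#' @param study A `pushrim_study`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  design <- study$design
  truth_all <- list()
  trials <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    gen <- generate_trial(row$recipe[[1]])
    fname <- sprintf("%s_%s_%s.csv", row$participant,
                     sub("_racket", "", row$condition),
                     substr(row$side, 1, 3))
    write_trial(gen$ts, file.path(dir, fname))
    wheel <- wheel_side(gen$ts)
    trials[[i]] <- list(participant = row$participant,
                        condition = row$condition, side = wheel,
                        file = fname, flip = identical(wheel, "left"))
    truth_all[[i]] <- mutate(gen$truth, participant = row$participant,
                             condition = row$condition, hand = row$side,
                             .before = 1)
  }
  # every participant's dominant hand is instrumented as the right wheel
  participants <- setNames(
    lapply(unique(design$participant), function(p) list(dominant_side = "right")),
    unique(design$participant)
  )
  manifest <- list(
    geometry = study$base_recipe$geometry[c("wheel_radius", "handrim_radius", "camber")],
    participants = participants,
    trials = trials
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  readr::write_csv(list_rbind(truth_all), file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(manifest_path)
}

#' @export
print.pushrim_study <- function(x, ...) {
  cat(sprintf("<synthetic 2x2 study: %d participants, %d trials, seed %d>\n",
              x$n_participants, nrow(x$design), x$seed))
  invisible(x)
}
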