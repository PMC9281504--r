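# Orchestration: load -> preprocess -> segment -> metrics -> summarize ->
# compare, producing the bilateral (2x2 ANOVA) and unilateral (paired t)
# comparison tables.

#' Analyze one wheel recording end to end
#'
#' Preprocesses (offset correction, smoothing, velocity), segments pushes
#' on the corrected total force, excludes transitional pushes, applies
#' optional review edits, computes the per-push metrics and the trial
#' summary.
#'
#' @param ts A [wheel_ts()].
#' @param geometry A [wheel_geometry()].
#' @param config A [pushrim_config()].
#' @param edits Optional segmentation review directives
#'   ([review_segmentation()]).
#' @return A list: `summary` (one-row tibble), `metrics` (per analyzed
#'   push), `pushes`, `velocity`, `offsets`.
#' @export
analyze_trial <- function(ts, geometry = wheel_geometry(),
                          config = pushrim_config(), edits = list()) {
  pre <- preprocess_trial(ts, geometry, config)
  ftot <- total_force(pre$ts)
  pushes <- detect_pushes(ftot, fs = wheel_fs(ts),
                          threshold = config$threshold_n,
                          min_push = config$min_push_s,
                          min_gap = config$min_gap_s)
  pushes <- exclude_transitional(pushes)
  if (length(edits) > 0) pushes <- review_segmentation(pushes, edits)
  metrics <- push_metrics(pre$ts, pushes, omega = pre$velocity$omega,
                          geometry = geometry, config = config)
  summary <- summarize_trial(metrics, pre$velocity)
  list(summary = summary, metrics = metrics, pushes = pushes,
       velocity = pre$velocity, offsets = pre$offsets)
}

resolve_hand <- function(side, dominant_side) {
  ifelse(side == dominant_side, "dominant", "nondominant")
}

#' Run the full 2x2 study pipeline
#'
#' Accepts a manifest path (see [read_manifest()]), an already-read
#' manifest list, or a `pushrim_study` (whose trials are synthesized in
#' memory). Each wheel recording is analyzed with [analyze_trial()], wheel
#' sides are relabeled to dominant/non-dominant per participant, and the
#' summaries are compared with [compare_panels()].
#'
#' @param x Manifest path, manifest list, or `pushrim_study`.
#' @param config A [pushrim_config()]; manifest `config:` overrides are
#'   applied on top.
#' @return A `pushrim_report`: list with `bilateral` and `unilateral`
#'   comparison tables, per-trial `summaries`, the resolved `config` and a
#'   plain-text `log`.
#' @export
run_study <- function(x, config = pushrim_config()) {
  log <- c(sprintf("config: %s",
                   paste(sprintf("%s=%s", names(unclass(config)),
                                 unlist(lapply(unclass(config), format))),
                         collapse = ", ")))
  if (inherits(x, "pushrim_study")) {
    geometry <- x$base_recipe$geometry
    rows <- list()
    for (i in seq_len(nrow(x$design))) {
      row <- x$design[i, ]
      gen <- generate_trial(row$recipe[[1]])
      res <- tryCatch(
        analyze_trial(gen$ts, geometry, config),
        pushrim_error_insufficient_pushes = function(e) {
          abort_pushrim(sprintf("trial %s/%s/%s: %s", row$participant,
                                row$condition, row$side, conditionMessage(e)),
                        class = "insufficient_pushes")
        }
      )
      log <- c(log, sprintf("trial %s %s %s: %d detected, %d analyzed",
                            row$participant, row$condition, row$side,
                            n_detected(res$pushes), n_analyzed(res$pushes)))
      rows[[i]] <- dplyr::bind_cols(
        tibble(participant = row$participant, condition = row$condition,
               side = row$side),
        select(res$summary, -"side")
      )
    }
    summaries <- list_rbind(rows)
  } else {
    manifest <- if (is.character(x)) read_manifest(x) else x
    config <- update_config(config, manifest$config)
    geometry <- manifest$geometry
    trials <- manifest$trials
    rows <- list()
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      dom <- manifest$dominant[[tr$participant]]
      if (is.null(dom)) {
        abort_pushrim(sprintf("no dominant side recorded for participant %s",
                              tr$participant), class = "completeness")
      }
      ts <- read_trial(tr$file, side = tr$side, flip = tr$flip)
      res <- tryCatch(
        analyze_trial(ts, geometry, config),
        pushrim_error_insufficient_pushes = function(e) {
          abort_pushrim(sprintf("trial %s/%s/%s: %s", tr$participant,
                                tr$condition, tr$side, conditionMessage(e)),
                        class = "insufficient_pushes")
        }
      )
      log <- c(log, sprintf("trial %s %s %s: %d detected, %d analyzed",
                            tr$participant, tr$condition, tr$side,
                            n_detected(res$pushes), n_analyzed(res$pushes)))
      rows[[i]] <- dplyr::bind_cols(
        tibble(participant = tr$participant, condition = tr$condition,
               side = resolve_hand(tr$side, dom)),
        select(res$summary, -"side")
      )
    }
    summaries <- list_rbind(rows)
  }
  report <- compare_panels(summaries, config)
  report$log <- c(log, report$log)
  report
}

check_design_complete <- function(summaries) {
  need <- tidyr::expand_grid(
    participant = unique(summaries$participant),
    condition = STUDY_CONDITIONS, side = STUDY_SIDES
  )
  have <- summaries[c("participant", "condition", "side")]
  miss <- dplyr::anti_join(need, have, by = c("participant", "condition", "side"))
  if (nrow(miss) > 0) {
    cells <- paste(sprintf("%s/%s/%s", miss$participant, miss$condition,
                           miss$side), collapse = "; ")
    abort_pushrim(paste0("incomplete 2x2 design, missing cells: ", cells),
                  class = "completeness")
  }
  dup <- summaries |>
    dplyr::count(.data$participant, .data$condition, .data$side) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_pushrim("duplicated design cells in summaries", class = "completeness")
  }
  invisible(summaries)
}

#' Compare per-trial summaries across the 2x2 design
#'
#' The statistical stage of the pipeline, applicable to any complete
#' per-trial summary table (from [run_study()], [study_summaries()] or
#' external data). Tests run on natural-log values; means, SDs and
#' Cohen's d are reported on the original scale.
#'
#' Bilateral table: per parameter, cell means/SDs, dominant-vs-nondominant
#' pooled-SD d within each condition, and the 2x2 repeated-measures ANOVA
#' (F, p, partial eta-squared for condition, side and interaction).
#' Unilateral table: dominant hand with vs without racket — paired t on
#' log values, Bonferroni-adjusted p, pooled-SD d.
#'
#' @param summaries Tibble with columns `participant`, `condition`
#'   (`with_racket`/`without_racket`), `side` (`dominant`/`nondominant`)
#'   and the nine parameter columns.
#' @param config A [pushrim_config()] (Bonferroni family size, d variant).
#' @return A `pushrim_report` list: `bilateral`, `unilateral`,
#'   `normality`, `summaries`, `config`, `log`.
#' @export
compare_panels <- function(summaries, config = pushrim_config()) {
  check_design_complete(summaries)
  params <- intersect(PARAMETERS, names(summaries))
  long <- summaries |>
    tidyr::pivot_longer(all_of(params), names_to = "parameter",
                        values_to = "value")

  cell_stats <- long |>
    group_by(.data$parameter, .data$condition, .data$side) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")

  # normality screen needs at least 3 participants per cell
  normality <- if (dplyr::n_distinct(summaries$participant) >= 3) {
    long |>
      group_by(.data$parameter, .data$condition, .data$side) |>
      summarise(as_tibble(shapiro_wilk(.data$value)), .groups = "drop")
  } else {
    NULL
  }

  bilateral <- purrr::map(params, function(pm) {
    cs <- filter(cell_stats, .data$parameter == pm)
    get <- function(cond, sd_col) {
      r <- filter(cs, .data$condition == cond)
      setNames(c(r$mean[r$side == "dominant"], r$sd[r$side == "dominant"],
                 r$mean[r$side == "nondominant"], r$sd[r$side == "nondominant"]),
               c("mean_d", "sd_d", "mean_nd", "sd_nd"))
    }
    w <- get("with_racket"); wo <- get("without_racket")
    panel <- long |>
      filter(.data$parameter == pm) |>
      mutate(value = log_transform(.data$value, pm))
    fit <- rm_anova_2x2(panel)
    eff <- fit$effects
    pick <- function(what, col) eff[[col]][eff$effect == what]
    tibble(
      parameter = pm,
      racket_d_mean = w[["mean_d"]], racket_d_sd = w[["sd_d"]],
      racket_nd_mean = w[["mean_nd"]], racket_nd_sd = w[["sd_nd"]],
      d_racket = cohens_d_pooled(w[["mean_d"]], w[["sd_d"]],
                                 w[["mean_nd"]], w[["sd_nd"]],
                                 method = config$d_variant),
      noracket_d_mean = wo[["mean_d"]], noracket_d_sd = wo[["sd_d"]],
      noracket_nd_mean = wo[["mean_nd"]], noracket_nd_sd = wo[["sd_nd"]],
      d_noracket = cohens_d_pooled(wo[["mean_d"]], wo[["sd_d"]],
                                   wo[["mean_nd"]], wo[["sd_nd"]],
                                   method = config$d_variant),
      f_condition = pick("condition", "statistic"),
      p_condition = pick("condition", "p.value"),
      eta2p_condition = pick("condition", "eta2p"),
      f_side = pick("side", "statistic"),
      p_side = pick("side", "p.value"),
      eta2p_side = pick("side", "eta2p"),
      f_interaction = pick("interaction", "statistic"),
      p_interaction = pick("interaction", "p.value"),
      eta2p_interaction = pick("interaction", "eta2p")
    )
  }) |> list_rbind()

  unilateral <- purrr::map(params, function(pm) {
    wide <- long |>
      filter(.data$parameter == pm, .data$side == "dominant") |>
      select("participant", "condition", "value") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "value")
    x_with <- wide$with_racket
    x_without <- wide$without_racket
    tt <- paired_t(log_transform(x_with, pm), log_transform(x_without, pm))
    cs <- filter(cell_stats, .data$parameter == pm, .data$side == "dominant")
    m_w <- cs$mean[cs$condition == "with_racket"]
    s_w <- cs$sd[cs$condition == "with_racket"]
    m_wo <- cs$mean[cs$condition == "without_racket"]
    s_wo <- cs$sd[cs$condition == "without_racket"]
    tibble(
      parameter = pm,
      with_mean = m_w, with_sd = s_w,
      without_mean = m_wo, without_sd = s_wo,
      statistic = tt$statistic, df = tt$parameter,
      p_raw = tt$p.value,
      p_adjusted = bonferroni(tt$p.value, config$bonferroni_m),
      d = cohens_d_pooled(m_w, s_w, m_wo, s_wo, method = config$d_variant),
      d_band = classify_effect_size(
        abs(cohens_d_pooled(m_w, s_w, m_wo, s_wo, method = config$d_variant)),
        "d")
    )
  }) |> list_rbind()

  structure(
    list(bilateral = bilateral, unilateral = unilateral,
         normality = normality, summaries = summaries, config = config,
         log = sprintf("compared %d parameters over %d participants",
                       length(params), dplyr::n_distinct(summaries$participant))),
    class = "pushrim_report"
  )
}

#' Check paced-speed compliance per trial
#'
#' @param summaries Per-trial summaries carrying a `velocity` column (m/s).
#' @param target Target speed, m/s.
#' @param tolerance Allowed absolute deviation, m/s.
#' @return The summaries with `pace_ok` (logical) and `pace_dev` columns.
#' @export
verify_pace <- function(summaries, target = 1.4, tolerance = 0.1) {
  check_number(target, "target", min = 0)
  check_number(tolerance, "tolerance", min = 0)
  mutate(summaries,
         pace_dev = .data$velocity - target,
         pace_ok = abs(.data$velocity - target) <= tolerance)
}

#' Round a comparison table to publication precision
#'
#' Means/SDs to 2 decimals, effect sizes (d, partial eta-squared) to 3,
#' F/t statistics to 3, p values to 3. Full precision stays in the
#' report object.
#'
#' @param report A `pushrim_report`.
#' @return List with rounded `bilateral` and `unilateral` tibbles.
#' @export
format_report <- function(report) {
  r2 <- function(x) round(x, 2)
  r3 <- function(x) round(x, 3)
  bi <- report$bilateral |>
    mutate(across(dplyr::matches("_mean$|_sd$"), r2),
           across(dplyr::matches("^d_|^f_|^p_|^eta2p_"), r3))
  un <- report$unilateral |>
    mutate(across(dplyr::matches("_mean$|_sd$"), r2),
           across(c("statistic", "p_raw", "p_adjusted", "d"), r3))
  list(bilateral = bi, unilateral = un)
}

#' @export
print.pushrim_report <- function(x, ...) {
  fr <- format_report(x)
  cat("Bilateral comparison (2x2 within-subject ANOVA):\n")
  print(as.data.frame(fr$bilateral[c("parameter", "d_racket", "d_noracket",
                                     "f_condition", "p_condition", "eta2p_condition",
                                     "f_side", "p_side", "eta2p_side",
                                     "f_interaction", "p_interaction",
                                     "eta2p_interaction")]),
        row.names = FALSE)
  cat("\nUnilateral comparison (dominant hand, with vs without racket):\n")
  print(as.data.frame(fr$unilateral), row.names = FALSE)
  invisible(x)
}

#' Tidy a study report into one row per parameter and effect
#'
#' @param x A `pushrim_report`.
#' @param ... Unused.
#' @return Long tibble: `parameter`, `contrast`, `statistic`, `p.value`,
#'   `effect_size`, `effect_size_kind`.
#' @method tidy pushrim_report
#' @export
tidy.pushrim_report <- function(x, ...) {
  bi <- x$bilateral
  long_bi <- purrr::map(c("condition", "side", "interaction"), function(e) {
    tibble(parameter = bi$parameter, contrast = e,
           statistic = bi[[paste0("f_", e)]],
           p.value = bi[[paste0("p_", e)]],
           effect_size = bi[[paste0("eta2p_", e)]],
           effect_size_kind = "eta2p")
  }) |> list_rbind()
  un <- tibble(parameter = x$unilateral$parameter, contrast = "paired",
               statistic = x$unilateral$statistic,
               p.value = x$unilateral$p_raw,
               effect_size = x$unilateral$d, effect_size_kind = "d")
  bind_rows(long_bi, un)
}

#' One-row overview of a study report
#'
#' @param x A `pushrim_report`.
#' @param ... Unused.
#' @return One-row tibble: participants, parameters, mean velocity,
#'   number of significant adjusted paired contrasts.
#' @method glance pushrim_report
#' @export
glance.pushrim_report <- function(x, ...) {
  tibble(
    n_participants = dplyr::n_distinct(x$summaries$participant),
    n_parameters = nrow(x$unilateral),
    mean_velocity = mean(x$summaries$velocity),
    n_signif_paired = sum(x$unilateral$p_adjusted < 0.05)
  )
}
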