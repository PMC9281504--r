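# The signal generator and its ground-truth bookkeeping.

test_that("the generator is deterministic given the seed", {
  a <- generate_trial(trial_recipe(seed = 99))
  b <- generate_trial(trial_recipe(seed = 99))
  expect_identical(a$ts, b$ts)
  expect_identical(a$truth, b$truth)
  c <- generate_trial(trial_recipe(seed = 100))
  expect_false(identical(a$ts$fx, c$ts$fx))
})

test_that("noise-free signals have exactly zero force between pushes", {
  gen <- generate_trial(trial_recipe(seed = 51, noise_sd = 0,
                                     moment_noise_sd = 0))
  ftot <- total_force(gen$ts)
  in_push <- rep(FALSE, nrow(gen$ts))
  for (i in seq_len(nrow(gen$truth))) {
    in_push[gen$truth$start_index[i]:gen$truth$end_index[i]] <- TRUE
  }
  # between detected pushes the clean force is below threshold; in the
  # coast lead-in/out it is exactly zero
  lead <- gen$ts$time < 0.9 | gen$ts$time > max(gen$ts$time) - 0.9
  expect_true(all(ftot[lead] == 0))
  expect_true(all(ftot >= 0))
})

test_that("the decomposed force channels reconstruct the intended resultant", {
  gen <- generate_trial(trial_recipe(seed = 52, noise_sd = 0,
                                     moment_noise_sd = 0))
  # resultant equals the half-sine envelope; fz carries 20% of the
  # non-tangential variance
  ftot <- total_force(gen$ts)
  i <- gen$truth$start_index[3]:gen$truth$end_index[3]
  tf <- gen$pushes$tangential_fraction[3]
  f_nt2 <- ftot[i]^2 * (1 - tf^2)
  expect_equal(gen$ts$fz[i]^2, 0.2 * f_nt2, tolerance = 1e-9)
  expect_equal(gen$ts$mz[i] / wheel_geometry()$handrim_radius / ftot[i],
               rep(tf, length(i)), tolerance = 1e-9)
})

test_that("a noise-free trial is recovered push-for-push from its ground truth", {
  rec <- trial_recipe(seed = 53, noise_sd = 0, moment_noise_sd = 0)
  gen <- generate_trial(rec)
  res <- analyze_trial(gen$ts, config = pushrim_config(offset_model = "none"))

  expect_equal(n_detected(res$pushes), 8)
  expect_equal(n_analyzed(res$pushes), 5)

  truth <- gen$truth[3:7, ]
  truth$ct_obs[5] <- NA_real_
  m <- res$metrics
  expect_equal(m$pt, truth$pt_obs, tolerance = 1e-12)       # exact samples
  expect_equal(m$ct, truth$ct_obs, tolerance = 1e-12)
  expect_equal(m$pa, truth$pa_obs, tolerance = 1e-9)
  expect_equal(m$ftot_peak, truth$ftot_peak, tolerance = 0.01)
  expect_equal(m$mz_peak, truth$mz_peak, tolerance = 0.01)
  expect_equal(m$fef, truth$fef, tolerance = 0.005 / 35)
  expect_equal(m$po_peak, truth$po_peak, tolerance = 0.01)
  expect_equal(m$ai, truth$ai_obs, tolerance = 0.01)
  expect_equal(m$ror, truth$ror_obs, tolerance = 0.02)
})

test_that("the pipeline FEF equals the injected tangential fraction", {
  rec <- trial_recipe(seed = 54,
                      variability = c(tangential_fraction = 0),
                      profile = push_profile(tangential_fraction = 0.35))
  gen <- generate_trial(rec)
  res <- analyze_trial(gen$ts)
  expect_equal(res$summary$fef, 35, tolerance = 0.5 / 35)
})

test_that("summary-level and signal-level generation share per-push parameters", {
  rec <- trial_recipe(seed = 55)
  gen <- generate_trial(rec)
  s <- trial_truth_summary(rec)
  truth <- gen$truth[3:7, ]
  expect_equal(s$ftot_peak, mean(truth$ftot_peak))
  expect_equal(s$fef, mean(truth$fef))
  expect_equal(s$ror, mean(truth$ror_obs))
  # continuous vs sample-exact observed times agree to within one sample
  expect_equal(s$pt, mean(truth$pt_obs), tolerance = (1 / FS) / s$pt)
})

test_that("invalid recipes are rejected", {
  expect_error(trial_recipe(n_pushes = 3), class = "pushrim_error_value")
  expect_error(push_profile(peak_force = 20), class = "pushrim_error_value")
  expect_error(push_profile(push_duration = 1.5, cycle_duration = 1.2),
               class = "pushrim_error_validation")
  expect_error(trial_recipe(variability = c(peak_force = -1)),
               class = "pushrim_error_validation")
})

test_that("study generation applies multiplicative cell effects", {
  eff <- study_effects(peak_force = c(condition = 1.36, side = 1.1,
                                      interaction = 1.05))
  st <- generate_study(n_participants = 4, effects = eff, seed = 3)
  d <- st$design
  base <- d$peak_force[d$condition == "without_racket" & d$side == "nondominant"]
  with_nd <- d$peak_force[d$condition == "with_racket" & d$side == "nondominant"]
  expect_equal(with_nd / base, rep(1.36, 4), tolerance = 1e-12)
  wo_d <- d$peak_force[d$condition == "without_racket" & d$side == "dominant"]
  expect_equal(wo_d / base, rep(1.1, 4), tolerance = 1e-12)
  with_d <- d$peak_force[d$condition == "with_racket" & d$side == "dominant"]
  expect_equal(with_d / base, rep(1.36 * 1.1 * 1.05, 4), tolerance = 1e-12)

  expect_equal(nrow(generate_study(n_participants = 2, seed = 1)$design), 8)
  expect_error(generate_study(n_participants = 1), class = "pushrim_error_value")
})

test_that("a written study reloads and analyzes end to end", {
  dir <- withr::local_tempdir()
  st <- generate_study(n_participants = 2, seed = 6,
                       base_recipe = trial_recipe(n_pushes = 6))
  manifest <- write_study(st, dir)
  expect_true(file.exists(manifest))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))

  rep <- run_study(manifest)
  expect_s3_class(rep$bilateral, "tbl_df")
  expect_equal(nrow(rep$summaries), 8)
  # dominant-hand trials came back from the right wheel, nondominant left
  expect_setequal(unique(rep$summaries$side), c("dominant", "nondominant"))
})
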