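# Per-push parameters against constructed signals and analytic forms.

test_that("peaks of constructed pushes are recovered exactly", {
  hp <- half_sine_push(peak = 80, pt = 0.4)
  expect_equal(ftot_peak(hp$ftot, hp$push), 80, tolerance = 1e-4)

  const <- list(start_index = 10, end_index = 100)
  expect_equal(ftot_peak(rep(50, 200), const), 50)

  mzs <- 20 * hp$ftot / hp$peak
  expect_equal(mz_peak(mzs, hp$push), 20, tolerance = 1e-4)
  expect_warning(mz_peak(rep(-2, 200), const), class = "pushrim_warning_qc")
})

test_that("rate of rise: exact on a ramp, analytic on a half-sine, zero on a constant", {
  # linear ramp 0 -> 100 N over 0.5 s embedded in a longer series
  ramp <- c(seq(0, 100, length.out = 121), rep(100, 100))
  p <- list(start_index = 1, end_index = 121)
  expect_equal(rate_of_rise(ramp[1:121], p, fs = FS), 200, tolerance = 1e-9)

  hp <- half_sine_push(peak = 80, pt = 0.4)
  seg <- hp$ftot[hp$push$start_index:hp$push$end_index]
  pseg <- list(start_index = 1, end_index = length(seg))
  expect_equal(rate_of_rise(seg, pseg, fs = FS), 80 * pi / 0.4,
               tolerance = 0.02)

  expect_equal(rate_of_rise(rep(50, 200), list(start_index = 20, end_index = 180),
                            fs = FS), 0, tolerance = 1e-9)
  expect_error(rate_of_rise(rep(50, 10), list(start_index = 1, end_index = 2),
                            fs = FS), class = "pushrim_error_short_push")
})

test_that("fef matches constructed ratios and flags impossible samples", {
  g <- wheel_geometry(handrim_radius = 0.26)
  n <- 100
  p <- list(start_index = 1, end_index = n)
  expect_equal(fef(rep(80, n), rep(10.4, n), p, g), 50)
  expect_equal(fef(rep(80, n), rep(80 * 0.26, n), p, g), 100)
  expect_equal(fef(rep(80, n), rep(0, n), p, g), 0)
  expect_error(fef(rep(0, n), rep(1, n), p, g),
               class = "pushrim_error_degenerate_push")
  expect_warning(fef(rep(80, n), rep(100 * 0.26, n), p, g),
                 class = "pushrim_warning_qc")
})

test_that("fef variants agree on proportional signals and differ otherwise", {
  hp <- half_sine_push(tf = 0.35)
  p <- hp$push
  g <- wheel_geometry(handrim_radius = hp$r)
  expect_equal(fef(hp$ftot, hp$mz, p, g, variant = "time_average"), 35,
               tolerance = 1e-9)
  expect_equal(fef(hp$ftot, hp$mz, p, g, variant = "ratio_of_means"), 35,
               tolerance = 1e-9)
  expect_equal(fef(hp$ftot, hp$mz, p, g, variant = "at_peak"), 35,
               tolerance = 1e-9)
})

test_that("peak power is the max of omega times mz", {
  hp <- half_sine_push()
  mzs <- 20 * hp$ftot / hp$peak
  expect_equal(po_peak(hp$omega, mzs, hp$push), 4.24 * 20, tolerance = 1e-4)
  expect_equal(po_peak(rep(0, length(mzs)), mzs, hp$push), 0)
})

test_that("angular impulse matches constants and the half-sine closed form", {
  p <- list(start_index = 1, end_index = 96)
  expect_equal(angular_impulse(rep(10, 96), p, fs = FS), 10 * 0.4)
  expect_equal(angular_impulse(rep(0, 96), p, fs = FS), 0)

  hp <- half_sine_push(peak = 10, pt = 0.4, tf = 1, r = 1)
  seg <- hp$ftot[hp$push$start_index:hp$push$end_index]
  ai <- angular_impulse(seg, list(start_index = 1, end_index = length(seg)),
                        fs = FS)
  expect_equal(ai, (2 / pi) * 10 * 0.4, tolerance = 0.005)
})

test_that("push, cycle time and push angle follow the index conventions", {
  p1 <- list(start_index = 1, end_index = 96)
  expect_equal(push_time(p1, fs = FS), 0.4)
  expect_equal(push_time(list(start_index = 5, end_index = 5), fs = FS), 1 / 240)

  p2 <- list(start_index = 289, end_index = 380)
  expect_equal(cycle_time(p1, p2, fs = FS), 1.2)
  expect_error(cycle_time(p2, p1, fs = FS), class = "pushrim_error_order")

  theta <- seq(0, pi / 2, length.out = 100)
  expect_equal(push_angle(theta, list(start_index = 1, end_index = 100)), 90)
  expect_equal(push_angle(rep(1, 100), list(start_index = 1, end_index = 100)), 0)
  expect_warning(push_angle(rev(theta), list(start_index = 1, end_index = 100)),
                 class = "pushrim_warning_qc")
})

test_that("doubling forces and moments scales the kinetic metrics and leaves times alone", {
  # metric homogeneity is a property of the parameters on a fixed push
  # interval (re-running the 30 N segmentation on doubled forces would of
  # course widen the detected pushes)
  rec <- trial_recipe(seed = 31, noise_sd = 0, moment_noise_sd = 0)
  gen <- generate_trial(rec)
  cfg <- pushrim_config(offset_model = "none")
  pre <- preprocess_trial(gen$ts, config = cfg)
  pushes <- exclude_transitional(
    detect_pushes(total_force(pre$ts), fs = FS)
  )
  base <- push_metrics(pre$ts, pushes, omega = pre$velocity$omega,
                       config = cfg)

  ts2 <- pre$ts
  for (ch in c("fx", "fy", "fz", "mx", "my", "mz")) ts2[[ch]] <- 2 * ts2[[ch]]
  doubled <- push_metrics(ts2, pushes, omega = pre$velocity$omega,
                          config = cfg)

  for (col in c("ftot_peak", "mz_peak", "ror", "po_peak", "ai")) {
    expect_equal(doubled[[col]], 2 * base[[col]], tolerance = 1e-9,
                 label = col)
  }
  for (col in c("fef", "pt", "ct", "pa")) {
    expect_equal(doubled[[col]], base[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("angular impulse never exceeds mz_peak times push time", {
  for (seed in 1:5) {
    gen <- generate_trial(trial_recipe(seed = seed))
    res <- analyze_trial(gen$ts)
    expect_true(all(res$metrics$ai <= res$metrics$mz_peak * res$metrics$pt + 1e-9))
  }
  # equality iff mz constant over the push
  p <- list(start_index = 1, end_index = 96)
  expect_equal(angular_impulse(rep(7, 96), p, FS),
               mz_peak(rep(7, 96), p) * push_time(p, FS))
})

test_that("trial summaries average per-push metrics and respect CT definition", {
  m <- tibble::tibble(
    push = 1:3, side = "right",
    ftot_peak = c(90, 100, 110), mz_peak = 10, ror = 800, fef = 35,
    po_peak = 40, ai = 2, pt = c(0.3, 0.4, 0.5), ct = c(1.1, 1.3, NA), pa = 65
  )
  s <- summarize_trial(m, velocity = rep(1.4, 100))
  expect_equal(s$pt, 0.4)
  expect_equal(s$ct, 1.2)  # mean over defined values only
  expect_equal(s$ftot_peak, 100)
  expect_equal(s$velocity, 1.4)
  expect_equal(s$n_analyzed, 3L)

  single <- summarize_trial(m[1, ] |> dplyr::mutate(ct = NA_real_), 1.4)
  expect_true(is.na(single$ct))
  expect_equal(single$ftot_peak, 90)
  expect_error(summarize_trial(m[0, ], 1.4),
               class = "pushrim_error_insufficient_pushes")
})
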