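# Offset estimation/removal and Savitzky-Golay velocity.

test_that("angular velocity of a linear angle is exact everywhere", {
  ts <- coast_ts(duration = 4, omega = 4.24)
  om <- angular_velocity(ts$theta, fs = FS)
  expect_equal(om, rep(4.24, length(om)), tolerance = 1e-10)
  # includes the reflected edges
  expect_equal(om[1], 4.24, tolerance = 1e-10)
  expect_equal(om[length(om)], 4.24, tolerance = 1e-10)

  om0 <- angular_velocity(rep(1.5, 2000), fs = FS)
  expect_equal(om0, rep(0, 2000), tolerance = 1e-12)
})

test_that("angular velocity tracks a quadratic angle in the interior", {
  t <- seq(0, 10, by = 1 / FS)
  theta <- 0.5 * 1.5 * t^2
  om <- angular_velocity(theta, fs = FS)
  interior <- 200:(length(t) - 200)
  expect_lt(max(abs(om[interior] - 1.5 * t[interior])), 1e-3)
})

test_that("the derivative filter is linear in its input", {
  withr::with_seed(9, {
    th1 <- cumsum(rnorm(1000))
    th2 <- cumsum(rnorm(1000))
  })
  a <- 2.5
  b <- -0.7
  lhs <- angular_velocity(a * th1 + b * th2, fs = FS)
  rhs <- a * angular_velocity(th1, fs = FS) + b * angular_velocity(th2, fs = FS)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("too-short series and bad windows raise errors", {
  expect_error(angular_velocity(rnorm(50), fs = FS, window = 131),
               class = "pushrim_error_length")
  expect_error(angular_velocity(rnorm(500), fs = FS, window = 130),
               class = "pushrim_error_value")
  expect_error(angular_velocity(rnorm(500), fs = FS, polyorder = 0),
               class = "pushrim_error_value")
})

test_that("linear velocity is omega times wheel radius", {
  g <- wheel_geometry()
  expect_equal(linear_velocity(4.24, g), 4.24 * 0.3302)
  expect_equal(linear_velocity(0, g), 0)
  # synthetic paced trial comes out at the target speed
  gen <- generate_trial(trial_recipe(seed = 5))
  res <- analyze_trial(gen$ts)
  expect_equal(res$summary$velocity, 1.4, tolerance = 0.005 / 1.4)
})

test_that("offset estimation recovers injected constants and harmonics", {
  off_in <- channel_offsets(c0 = c(fx = 5), a = c(fz = 3 * cos(pi / 6)),
                            b = c(fz = 3 * sin(pi / 6)))
  rec <- trial_recipe(seed = 7, noise_sd = 0, moment_noise_sd = 0,
                      offsets = off_in)
  gen <- generate_trial(rec)
  mask <- noncontact_mask(gen$ts, threshold = 30)
  est <- estimate_offsets(gen$ts, mask)

  expect_equal(est$c0[est$channel == "fx"], 5, tolerance = 1e-6)
  expect_equal(est$a[est$channel == "fz"], 3 * cos(pi / 6), tolerance = 1e-6)
  expect_equal(est$b[est$channel == "fz"], 3 * sin(pi / 6), tolerance = 1e-6)
  expect_equal(est$c0[est$channel == "my"], 0, tolerance = 1e-9)

  # independent normal-equations oracle on the same masked samples
  orc <- oracle_harmonic_fit(gen$ts$theta[mask], gen$ts$fz[mask])
  expect_equal(est$a[est$channel == "fz"], unname(orc["a"]), tolerance = 1e-9)
  expect_equal(est$b[est$channel == "fz"], unname(orc["b"]), tolerance = 1e-9)

  # offset-free trial: everything is zero
  gen0 <- generate_trial(trial_recipe(seed = 7, noise_sd = 0,
                                      moment_noise_sd = 0))
  est0 <- estimate_offsets(gen0$ts, noncontact_mask(gen0$ts))
  expect_lt(max(abs(as.matrix(est0[c("c0", "a", "b")]))), 1e-9)
})

test_that("offset estimation recovers any signal in span{1, sin, cos} exactly", {
  ts <- coast_ts(duration = 4)
  withr::with_seed(11, {
    for (i in 1:5) {
      cf <- rnorm(3, sd = 4)
      ts2 <- ts
      ts2$mx <- cf[1] + cf[2] * sin(ts$theta) + cf[3] * cos(ts$theta)
      est <- estimate_offsets(ts2, rep(TRUE, nrow(ts2)))
      got <- unlist(est[est$channel == "mx", c("c0", "a", "b")])
      expect_equal(unname(got), cf, tolerance = 1e-9)
    }
  })
})

test_that("estimate-then-remove brings coasting forces below the noise floor", {
  off_in <- channel_offsets(c0 = c(fy = 4), a = c(fy = 2), b = c(fx = -3))
  rec <- trial_recipe(seed = 13, noise_sd = 1, offsets = off_in)
  gen <- generate_trial(rec)
  mask <- noncontact_mask(gen$ts, threshold = 30)
  corrected <- remove_offsets(gen$ts, estimate_offsets(gen$ts, mask))
  expect_lt(sqrt(mean(corrected$fy[mask]^2)), 1.05)  # ~noise SD of 1 N
  expect_lt(sqrt(mean(corrected$fx[mask]^2)), 1.05)
})

test_that("removing all-zero offsets is the identity; twice is not once", {
  gen <- generate_trial(trial_recipe(seed = 15))
  zero <- channel_offsets()
  same <- remove_offsets(gen$ts, zero)
  expect_equal(same$fx, gen$ts$fx)

  off <- channel_offsets(c0 = c(fx = 5))
  once <- remove_offsets(gen$ts, off)
  twice <- remove_offsets(once, off)
  expect_equal(unique(round(once$fx - twice$fx, 9)), 5)
})

test_that("a zero-offset round trip leaves push metrics untouched", {
  rec <- trial_recipe(seed = 16, noise_sd = 0, moment_noise_sd = 0)
  gen <- generate_trial(rec)
  cfg <- pushrim_config(offset_model = "none", smooth_window = 0)
  before <- analyze_trial(gen$ts, config = cfg)
  ts2 <- remove_offsets(gen$ts, channel_offsets())
  after <- analyze_trial(ts2, config = cfg)
  expect_equal(after$metrics, before$metrics)
})

test_that("insufficient mask coverage raises a coverage error", {
  ts <- coast_ts(duration = 4)
  expect_error(estimate_offsets(ts, c(rep(TRUE, 50), rep(FALSE, nrow(ts) - 50))),
               class = "pushrim_error_coverage")
  # 200 samples spanning < 1 revolution
  short <- rep(FALSE, nrow(ts))
  short[1:200] <- TRUE  # 200 / 240 s * 4.24 rad/s ~ 3.5 rad < 2*pi
  expect_error(estimate_offsets(ts, short), class = "pushrim_error_coverage")
})
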