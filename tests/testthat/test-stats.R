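# Statistical operations: transforms, tests, effect sizes, the 2x2 ANOVA.

test_that("log transform inverts exp, rejects non-positive input, keeps order", {
  expect_equal(log_transform(exp(2.5)), 2.5)
  expect_error(log_transform(c(1, 0, 2), name = "fef"),
               class = "pushrim_error_domain")
  x <- c(3, 1, 10, 7)
  expect_equal(order(log_transform(x)), order(x))
})

test_that("shapiro_wilk flags a known non-normal sample and guards input", {
  # classic right-skewed sample; W value frozen from the Royston algorithm
  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  res <- shapiro_wilk(x)
  expect_equal(res$statistic, 0.79, tolerance = 0.01)
  expect_lt(res$p.value, 0.05)

  expect_error(shapiro_wilk(rep(5, 10)), class = "pushrim_error_degenerate")
  expect_error(shapiro_wilk(c(1, 2)), class = "pushrim_error_size")
})

test_that("shapiro_wilk holds its nominal type-I error on normal samples", {
  reject <- withr::with_seed(3, {
    mean(replicate(2000, shapiro_wilk(rnorm(16))$p.value < 0.05))
  })
  expect_gt(reject, 0.035)
  expect_lt(reject, 0.065)
})

test_that("paired_t matches the hand formula and its symmetries", {
  x0 <- c(1, 2, 3, 4)
  x1 <- rep(0, 4)
  res <- paired_t(x0, x1)
  expect_equal(res$statistic, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(res$statistic, 3.873, tolerance = 1e-3)
  expect_equal(res$parameter, 3)

  flipped <- paired_t(x1, x0)
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p.value, res$p.value)

  expect_error(paired_t(x0, x0), class = "pushrim_error_degenerate")
  # agrees with t.test
  withr::with_seed(4, {
    a <- rlnorm(12); b <- rlnorm(12)
  })
  ours <- paired_t(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("pooled-SD Cohen's d reproduces published table values", {
  expect_equal(cohens_d_pooled(117.77, 45.36, 86.53, 38.65), 0.741,
               tolerance = 0.001)
  expect_equal(cohens_d_pooled(29.36, 6.93, 35.82, 10.94), 0.705,
               tolerance = 0.001)
  expect_equal(cohens_d_pooled(5, 1, 5, 2), 0)
  expect_error(cohens_d_pooled(1, 0, 2, 0), class = "pushrim_error_degenerate")
})

test_that("cohens_d_pooled is symmetric and scale-invariant", {
  withr::with_seed(5, {
    for (i in 1:20) {
      m <- rlnorm(2, 3); s <- rlnorm(2); a <- rlnorm(1)
      d1 <- cohens_d_pooled(m[1], s[1], m[2], s[2])
      expect_equal(cohens_d_pooled(m[2], s[2], m[1], s[1]), d1)
      expect_equal(cohens_d_pooled(a * m[1], a * s[1], a * m[2], a * s[2]), d1)
    }
  })
})

test_that("partial eta squared and bonferroni follow their definitions", {
  expect_equal(partial_eta_squared(1, 3), 0.25)
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_equal(partial_eta_squared(5, 0), 1)
  expect_error(partial_eta_squared(0, 0), class = "pushrim_error_degenerate")

  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.4, 5), 1)
  expect_equal(bonferroni(c(0.2, 0.01, 0.04), 1), c(0.2, 0.01, 0.04))
  p <- c(0.001, 0.04, 0.2)
  expect_equal(order(bonferroni(p, 3)), order(p))
})

test_that("effect sizes fall into the conventional bands", {
  expect_equal(classify_effect_size(0.741, "d"), "moderate")
  expect_equal(classify_effect_size(0.148, "eta2p"), "large")
  expect_equal(classify_effect_size(0, "d"), "below_small")
  expect_equal(classify_effect_size(0.2, "d"), "small")
  expect_equal(classify_effect_size(0.8, "d"), "large")
  expect_equal(classify_effect_size(0.06, "eta2p"), "moderate")
  expect_error(classify_effect_size(0.5, "r"))
})

test_that("degenerate panels produce the expected zero effects", {
  # all four cells equal within participant, differing across participants
  panel <- make_panel(n = 6, seed = 8)
  panel <- panel |>
    dplyr::group_by(participant) |>
    dplyr::mutate(value = value[1]) |>
    dplyr::ungroup()
  fit <- tidy(rm_anova_2x2(panel))
  expect_equal(fit$statistic, rep(0, 3), tolerance = 1e-20)
  expect_equal(fit$eta2p, rep(0, 3), tolerance = 1e-20)

  # pure additive condition effect, no noise
  panel2 <- make_panel(n = 6, seed = 9)
  panel2 <- panel2 |>
    dplyr::group_by(participant) |>
    dplyr::mutate(value = value[1] + 2 * (condition == "with_racket")) |>
    dplyr::ungroup()
  fit2 <- tidy(rm_anova_2x2(panel2))
  expect_equal(fit2$eta2p[fit2$effect == "condition"], 1)
  expect_equal(fit2$ss_effect[fit2$effect == "side"], 0, tolerance = 1e-20)
  expect_equal(fit2$ss_effect[fit2$effect == "interaction"], 0,
               tolerance = 1e-20)
})

test_that("rm_anova_2x2 equals the brute-force oracle on random panels", {
  for (seed in 1:25) {
    panel <- make_panel(n = 8, seed = seed)
    got <- tidy(rm_anova_2x2(panel))
    want <- oracle_rm_anova(panel)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df2, want$df2)
    expect_equal(got$eta2p, want$eta2p, tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  }
})

test_that("rm_anova_2x2 matches aov error strata on one panel", {
  panel <- make_panel(n = 10, seed = 77)
  got <- tidy(rm_anova_2x2(panel))
  df <- as.data.frame(panel)
  df$participant <- factor(df$participant)
  fit <- stats::aov(value ~ condition * side +
                      Error(participant / (condition * side)), data = df)
  s <- summary(fit)
  f_aov <- c(
    s[["Error: participant:condition"]][[1]]["condition", "F value"],
    s[["Error: participant:side"]][[1]]["side", "F value"],
    s[["Error: participant:condition:side"]][[1]]["condition:side", "F value"]
  )
  expect_equal(got$statistic, unname(f_aov), tolerance = 1e-10)
})

test_that("each 2-level factor's F equals the squared paired t on marginal means", {
  for (seed in 1:10) {
    panel <- make_panel(n = 9, seed = 100 + seed)
    got <- tidy(rm_anova_2x2(panel))
    marg <- panel |>
      dplyr::group_by(participant, condition) |>
      dplyr::summarise(value = mean(value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = condition, values_from = value)
    t_cond <- paired_t(marg$with_racket, marg$without_racket)
    expect_equal(got$statistic[got$effect == "condition"],
                 t_cond$statistic^2, tolerance = 1e-9)
    expect_equal(got$p.value[got$effect == "condition"], t_cond$p.value,
                 tolerance = 1e-9)

    marg2 <- panel |>
      dplyr::group_by(participant, side) |>
      dplyr::summarise(value = mean(value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = side, values_from = value)
    t_side <- paired_t(marg2$dominant, marg2$nondominant)
    expect_equal(got$statistic[got$effect == "side"], t_side$statistic^2,
                 tolerance = 1e-9)
  }
})

test_that("incomplete panels are rejected", {
  panel <- make_panel(n = 5, seed = 12)
  expect_error(rm_anova_2x2(panel[-3, ]), class = "pushrim_error_completeness")
  expect_error(rm_anova_2x2(panel[panel$participant == "s01", ]),
               class = "pushrim_error_completeness")
})
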