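# Two-way fully-within-subject (2x2 repeated measures) ANOVA.
#
# The sums of squares are partitioned into subject, condition, side,
# condition:side, and the three effect-by-subject error strata. Each
# within effect is tested against its own interaction with subject:
# F = MS_effect / MS_(effect x subject). With two levels per factor every
# effect has one numerator df, sphericity holds trivially, and the
# Greenhouse-Geisser epsilon is exactly 1 (it is still carried and applied
# so the correction generalizes mechanically).

#' 2x2 within-subject repeated-measures ANOVA
#'
#' @param panel Long-format data with one row per participant x cell:
#'   columns `participant`, `condition` (2 levels), `side` (2 levels) and
#'   `value`. Complete cases only: every participant must contribute all
#'   four cells exactly once, and at least 2 participants are required.
#'
#' @return An object of class `pushrim_rm_anova`; use [tidy()] for the
#'   per-effect table (`effect`, `ss_effect`, `ss_error`, `df1`, `df2`,
#'   `epsilon`, `statistic`, `p.value`, `eta2p`) and [glance()] for the
#'   design summary.
#' @export
#' @examples
#' panel <- expand.grid(participant = 1:6,
#'                      condition = c("a", "b"), side = c("d", "n"))
#' panel$value <- rlnorm(nrow(panel))
#' tidy(rm_anova_2x2(panel))
rm_anova_2x2 <- function(panel) {
  req <- c("participant", "condition", "side", "value")
  missing <- setdiff(req, names(panel))
  if (length(missing) > 0) {
    abort_pushrim(paste0("panel is missing columns: ", paste(missing, collapse = ", ")),
                  class = "format")
  }
  panel <- as_tibble(panel)
  conds <- sort(unique(as.character(panel$condition)))
  sides <- sort(unique(as.character(panel$side)))
  if (length(conds) != 2 || length(sides) != 2) {
    abort_pushrim("`condition` and `side` must each have exactly 2 levels",
                  class = "format")
  }
  counts <- table(panel$participant, panel$condition, panel$side)
  if (any(counts != 1)) {
    abort_pushrim("incomplete panel: every participant needs all four cells exactly once",
                  class = "completeness")
  }
  subjects <- sort(unique(as.character(panel$participant)))
  n <- length(subjects)
  if (n < 2) {
    abort_pushrim("need at least 2 participants", class = "completeness")
  }

  # y[subject, condition, side]
  y <- array(NA_real_, dim = c(n, 2, 2),
             dimnames = list(subjects, conds, sides))
  y[cbind(match(as.character(panel$participant), subjects),
          match(as.character(panel$condition), conds),
          match(as.character(panel$side), sides))] <- panel$value

  g <- mean(y)
  m_s <- apply(y, 1, mean)       # subject means
  m_a <- apply(y, 2, mean)       # condition means
  m_b <- apply(y, 3, mean)       # side means
  m_ab <- apply(y, c(2, 3), mean)
  m_as <- apply(y, c(1, 2), mean)
  m_bs <- apply(y, c(1, 3), mean)

  ss_subj <- 4 * sum((m_s - g)^2)
  ss_a <- 2 * n * sum((m_a - g)^2)
  ss_b <- 2 * n * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + g)^2)
  ss_as <- 2 * sum((m_as - outer(m_s, m_a, "+") + g)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_s, m_b, "+") + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)

  epsilon <- 1  # two-level factors: sphericity holds, GG epsilon is exactly 1
  eff <- tibble(
    effect = c("condition", "side", "interaction"),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs),
    df1 = 1,
    df2 = n - 1,
    epsilon = epsilon
  )
  eff <- mutate(
    eff,
    # a strictly zero effect SS is a zero effect even when its error
    # stratum is also empty (0/0): F = 0, eta2p = 0
    statistic = ifelse(.data$ss_effect == 0, 0,
                       (.data$ss_effect / .data$df1) /
                         (.data$ss_error / .data$df2)),
    p.value = stats::pf(.data$statistic, .data$df1 * epsilon,
                        .data$df2 * epsilon, lower.tail = FALSE),
    eta2p = ifelse(.data$ss_effect == 0, 0,
                   .data$ss_effect / (.data$ss_effect + .data$ss_error))
  )

  structure(
    list(effects = eff, n = n, ss_subject = ss_subj, ss_total = ss_tot,
         cell_means = m_ab, conditions = conds, sides = sides),
    class = "pushrim_rm_anova"
  )
}

#' @export
print.pushrim_rm_anova <- function(x, ...) {
  cat(sprintf("2x2 within-subject ANOVA (n = %d, GG epsilon = 1)\n", x$n))
  print(as.data.frame(x$effects), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a 2x2 repeated-measures ANOVA
#'
#' @param x A `pushrim_rm_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per within effect.
#' @method tidy pushrim_rm_anova
#' @export
tidy.pushrim_rm_anova <- function(x, ...) x$effects

#' One-line design summary of a 2x2 repeated-measures ANOVA
#'
#' @param x A `pushrim_rm_anova` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `epsilon`, `ss_subject`, `ss_total`.
#' @method glance pushrim_rm_anova
#' @export
glance.pushrim_rm_anova <- function(x, ...) {
  tibble(n = x$n, epsilon = 1, ss_subject = x$ss_subject, ss_total = x$ss_total)
}
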