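# Statistical toolbox for the 2x2 within-subject comparison:
# log transform -> normality screen -> RM-ANOVA / paired t on log data,
# with effect sizes (partial eta-squared, pooled-SD Cohen's d) computed on
# the untransformed summaries.

#' Natural-log transform of a positive parameter
#'
#' All nine outcome parameters are strictly positive, so tests are run on
#' natural-log data (the base only rescales, it never changes a test).
#'
#' @param x Numeric vector, all values > 0.
#' @param name Parameter name used in the error message.
#' @return `log(x)`.
#' @export
log_transform <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort_pushrim(
      sprintf("`%s` has non-positive values; cannot log-transform", name),
      class = "domain"
    )
  }
  log(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin, defensive wrapper around the standard Royston approximation:
#' rejects degenerate (constant) input and sample sizes outside [3, 5000]
#' with typed errors instead of opaque failures.
#'
#' @param x Numeric vector, 3 to 5000 values.
#' @return A tibble with `statistic` (W) and `p.value`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) {
    abort_pushrim(sprintf("Shapiro-Wilk needs 3 <= n <= 5000 (got %d)", n),
                  class = "size")
  }
  if (sd(x) == 0) {
    abort_pushrim("Shapiro-Wilk is undefined for constant input",
                  class = "degenerate")
  }
  res <- stats::shapiro.test(x)
  tibble(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = x0 - x1`, with `n - 1` degrees of freedom and a two-sided p value.
#'
#' @param x0,x1 Paired observations of equal length (n >= 2).
#' @return A tibble with `statistic` (t), `parameter` (df) and `p.value`.
#' @export
paired_t <- function(x0, x1) {
  if (length(x0) != length(x1) || length(x0) < 2) {
    abort_pushrim("`x0` and `x1` must be paired vectors of equal length >= 2",
                  class = "size")
  }
  d <- x0 - x1
  s <- sd(d)
  if (s == 0) {
    abort_pushrim("paired differences have zero variance", class = "degenerate")
  }
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  tibble(statistic = t, parameter = n - 1,
         p.value = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Pooled-SD Cohen's d from group summaries
#'
#' Standardized mean difference `|m0 - m1| / sqrt((s0^2 + s1^2) / 2)`,
#' the form that reproduces published comparison tables from their own
#' printed means and SDs. The alternative `"reference"` form divides by
#' `s0` (the SD of the reference group) instead.
#'
#' @param m0,s0 Mean and SD of the reference group (e.g. without racket,
#'   or dominant hand).
#' @param m1,s1 Mean and SD of the other group.
#' @param method `"pooled"` (default) or `"reference"`.
#' @return Non-negative effect size d (for `"reference"`, the signed
#'   `(m0 - m1)/s0`).
#' @export
cohens_d_pooled <- function(m0, s0, m1, s1, method = c("pooled", "reference")) {
  method <- match.arg(method)
  if (s0 < 0 || s1 < 0 || (s0 == 0 && s1 == 0)) {
    abort_pushrim("group SDs must be >= 0 and not both zero", class = "degenerate")
  }
  if (method == "reference") {
    if (s0 == 0) abort_pushrim("reference SD is zero", class = "degenerate")
    return((m0 - m1) / s0)
  }
  abs(m0 - m1) / sqrt((s0^2 + s1^2) / 2)
}

#' Partial eta-squared
#'
#' `ss_effect / (ss_effect + ss_error)` for one effect of a
#' repeated-measures ANOVA.
#'
#' @param ss_effect,ss_error Sums of squares, both >= 0, not both 0.
#' @return Effect size in [0, 1].
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0) {
    abort_pushrim("sums of squares must be non-negative", class = "value")
  }
  if (ss_effect + ss_error == 0) {
    abort_pushrim("both sums of squares are zero", class = "degenerate")
  }
  ss_effect / (ss_effect + ss_error)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, p * m)`. The family size is explicit because the
#' relevant family (the simple-effect contrasts of the 2x2 design) is not
#' the length of the vector being adjusted.
#'
#' @param p P values in [0, 1].
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p values, order-preserving.
#' @export
bonferroni <- function(p, m) {
  check_number(m, "m", min = 1)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_pushrim("p values must lie in [0, 1]", class = "value")
  }
  pmin(1, p * m)
}

#' Classify an effect size into conventional bands
#'
#' Cohen's bands: for d, small 0.2, moderate 0.5, large 0.8; for partial
#' eta-squared, small 0.01, medium 0.06, large 0.14. Thresholds are
#' inclusive; values below the small threshold are `"below_small"`.
#'
#' @param value Non-negative effect size.
#' @param kind `"d"` or `"eta2p"`.
#' @return One of `"below_small"`, `"small"`, `"moderate"`, `"large"`.
#' @export
classify_effect_size <- function(value, kind = c("d", "eta2p")) {
  kind <- match.arg(kind)
  check_number(value, "value", min = 0)
  cuts <- if (kind == "d") c(0.2, 0.5, 0.8) else c(0.01, 0.06, 0.14)
  bands <- c("below_small", "small", "moderate", "large")
  bands[findInterval(value, cuts) + 1]
}
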