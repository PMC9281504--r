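# Independent oracles, deliberately written as explicit per-observation
# sums so they share no code with the implementation.

# brute-force within-subject SS decomposition for a 2x2 design
oracle_rm_anova <- function(panel) {
  subj <- sort(unique(as.character(panel$participant)))
  conds <- sort(unique(as.character(panel$condition)))
  sides <- sort(unique(as.character(panel$side)))
  val <- function(i, j, k) {
    panel$value[panel$participant == subj[i] & panel$condition == conds[j] &
                  panel$side == sides[k]]
  }
  n <- length(subj)
  g <- mean(panel$value)
  ss <- c(condition = 0, side = 0, interaction = 0,
          err_condition = 0, err_side = 0, err_interaction = 0)
  for (i in seq_len(n)) {
    for (j in 1:2) {
      for (k in 1:2) {
        m_s <- mean(c(val(i, 1, 1), val(i, 1, 2), val(i, 2, 1), val(i, 2, 2)))
        m_a <- mean(panel$value[panel$condition == conds[j]])
        m_b <- mean(panel$value[panel$side == sides[k]])
        m_ab <- mean(panel$value[panel$condition == conds[j] &
                                   panel$side == sides[k]])
        m_as <- mean(c(val(i, j, 1), val(i, j, 2)))
        m_bs <- mean(c(val(i, 1, k), val(i, 2, k)))
        y <- val(i, j, k)
        ss["condition"] <- ss["condition"] + (m_a - g)^2
        ss["side"] <- ss["side"] + (m_b - g)^2
        ss["interaction"] <- ss["interaction"] + (m_ab - m_a - m_b + g)^2
        ss["err_condition"] <- ss["err_condition"] + (m_as - m_s - m_a + g)^2
        ss["err_side"] <- ss["err_side"] + (m_bs - m_s - m_b + g)^2
        ss["err_interaction"] <- ss["err_interaction"] +
          (y - m_as - m_bs - m_ab + m_a + m_b + m_s - g)^2
      }
    }
  }
  out <- data.frame(
    effect = c("condition", "side", "interaction"),
    ss_effect = ss[c("condition", "side", "interaction")],
    ss_error = ss[c("err_condition", "err_side", "err_interaction")],
    row.names = NULL
  )
  out$df1 <- 1
  out$df2 <- n - 1
  out$statistic <- (out$ss_effect / out$df1) / (out$ss_error / out$df2)
  out$p.value <- stats::pf(out$statistic, out$df1, out$df2, lower.tail = FALSE)
  out$eta2p <- out$ss_effect / (out$ss_effect + out$ss_error)
  out
}

# least-squares fit of c0 + a sin(theta) + b cos(theta) via the normal
# equations, independent of lm.fit
oracle_harmonic_fit <- function(theta, y) {
  X <- cbind(1, sin(theta), cos(theta))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(c0 = beta[1], a = beta[2], b = beta[3])
}
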