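# Fixtures built in code: small wheel series and half-sine pushes.

FS <- 240

# a quiet coasting series: constant angular velocity, zero forces
coast_ts <- function(duration = 4, omega = 4.24, fs = FS, side = "right") {
  t <- seq(0, duration, by = 1 / fs)
  wheel_ts(
    data.frame(time = t, fx = 0, fy = 0, fz = 0, mx = 0, my = 0, mz = 0,
               theta = omega * t),
    side = side, fs = fs
  )
}

# standalone half-sine push series: samples strictly inside (0, pt) carry
# force; the push interval is the full set of non-zero samples
half_sine_push <- function(peak = 100, pt = 0.4, fs = FS, lead = 0.5,
                           tf = 0.35, r = 0.267, omega = 4.24) {
  t <- seq(0, pt + 2 * lead, by = 1 / fs)
  inp <- t > lead & t < lead + pt
  f <- ifelse(inp, peak * sin(pi * (t - lead) / pt), 0)
  mz <- tf * f * r
  idx <- which(inp)
  list(
    t = t, ftot = f, mz = mz, theta = omega * t,
    omega = rep(omega, length(t)),
    push = list(start_index = idx[1], end_index = idx[length(idx)]),
    peak = peak, pt_nominal = pt, tf = tf, r = r,
    pt_sampled = length(idx) / fs
  )
}

# a simple 2x2 panel in long format
make_panel <- function(n = 8, seed = 1, fun = function(m) stats::rlnorm(m)) {
  withr::with_seed(seed, {
    panel <- tidyr::expand_grid(
      participant = sprintf("s%02d", seq_len(n)),
      condition = c("with_racket", "without_racket"),
      side = c("dominant", "nondominant")
    )
    panel$value <- fun(nrow(panel))
    panel
  })
}
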