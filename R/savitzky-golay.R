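# Savitzky-Golay smoothing/differentiation with point-symmetric edges.
#
# Filter coefficients come from signal::sgolay; the edge policy is written
# here because the transient-fit edges of signal::sgolayfilt are replaced by
# point-symmetric (odd) reflection about the end samples. Odd reflection
# continues a locally linear signal exactly, so the derivative of a straight
# line is exact out to the very first and last sample — the property the
# wheel-angle channel (nearly linear in time) relies on.

# odd (point-symmetric) reflection pad: x[0] - (x[k+1] - x[0]) on the left
pad_reflect_odd <- function(x, k) {
  n <- length(x)
  if (k <= 0) return(x)
  if (k >= n) {
    abort_pushrim("series too short for the requested filter window", class = "length")
  }
  c(2 * x[1] - x[(k + 1):2], x, 2 * x[n] - x[(n - 1):(n - k)])
}

# apply the central SG filter row over an odd-reflected series
sg_filter <- function(x, window, polyorder, deriv, fs) {
  if (!is_odd(window) || window < 3) {
    abort_pushrim("`window` must be an odd integer >= 3", class = "value")
  }
  if (polyorder < deriv || polyorder >= window) {
    abort_pushrim("need deriv <= polyorder < window", class = "value")
  }
  if (length(x) < window) {
    abort_pushrim(
      sprintf("series length %d is shorter than the %d-sample window",
              length(x), window),
      class = "length"
    )
  }
  h <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = 1 / fs)
  h <- h[(window + 1) / 2, ]  # central (steady-state) filter row
  k <- (window - 1) / 2
  xp <- pad_reflect_odd(x, k)
  out <- stats::filter(xp, rev(h), sides = 2)
  as.numeric(out[(k + 1):(k + length(x))])
}

sg_smooth <- function(x, window, polyorder, fs) {
  sg_filter(x, window, polyorder, deriv = 0, fs = fs)
}

sg_derivative <- function(x, window, polyorder, fs) {
  sg_filter(x, window, polyorder, deriv = 1, fs = fs)
}
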