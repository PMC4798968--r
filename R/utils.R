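# Internal helpers shared across modules.

# Linear interpolation that insists the query points are covered by the data.
interp_at <- function(x, y, xout, what = "trace") {
  if (min(xout) < min(x) - 1e-12 || max(xout) > max(x) + 1e-12) {
    abort(sprintf(
      "requested times [%g, %g] s are not covered by the %s ([%g, %g] s)",
      min(xout), max(xout), what, min(x), max(x)
    ), class = "primekin_input_error")
  }
  approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be a positive finite number", name),
          class = "primekin_input_error")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name),
          class = "primekin_input_error")
  }
  invisible(x)
}

# Trapezoidal integral (used for spike charge; pA * s = pC).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
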