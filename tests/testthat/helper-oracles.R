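# Independent oracles for the kinetic model, written directly from the
# model's chemical scheme rather than sharing code with the package.

# Pool derivatives at fixed rate constants (f held fixed by the caller or
# evolved alongside).  State: c(D, N, R, RC, RC2, RC3, F, f).
oracle_deriv <- function(y, ca, p) {
  f <- y[8]
  k1 <- f * p$k1_max
  g <- ca / (p$K_D_cat + ca)
  k2 <- p$k_20 + g * p$k_2cat
  km2 <- p$k_minus20 + g * (p$k_minus20 * p$k_2cat / p$k_20)
  kb <- p$k_3 * ca
  ku <- p$k_minus3
  c(
    p$k_minus1 * y[2] - k1 * y[1],
    k1 * y[1] + km2 * y[3] - (p$k_minus1 + k2) * y[2],
    k2 * y[2] + ku * y[4] - (km2 + 3 * kb) * y[3],
    3 * kb * y[3] + 2 * ku * y[5] - (ku + 2 * kb) * y[4],
    2 * kb * y[4] + 3 * ku * y[6] - (2 * ku + kb) * y[5],
    kb * y[5] - (3 * ku + p$k_4) * y[6],
    p$k_4 * y[6],
    p$k_on * (1 - f) * ca^p$n - p$k_on * p$K_D^p$n * f
  )
}

# Classical fixed-step fourth-order Runge-Kutta integration of the full
# system along a Ca2+ trace, reporting the state at the requested times.
oracle_rk4 <- function(trace, p, y0, h = 1e-4, times_out) {
  caf <- approxfun(trace$time_s, trace$ca_um, rule = 2)
  t <- trace$time_s[1]
  t_end <- max(times_out)
  y <- y0
  out <- matrix(NA_real_, nrow = length(times_out), ncol = 8)
  # record by linear interpolation between consecutive RK4 states
  prev_t <- t
  prev_y <- y
  next_i <- 1L
  record <- function(next_i, t0, y0v, t1, y1v) {
    while (next_i <= length(times_out) && times_out[next_i] <= t1 + 1e-12) {
      w <- if (t1 > t0) (times_out[next_i] - t0) / (t1 - t0) else 0
      out[next_i, ] <<- (1 - w) * y0v + w * y1v
      next_i <- next_i + 1L
    }
    next_i
  }
  next_i <- record(next_i, t - 1, y, t, y)
  while (t < t_end - 1e-12) {
    hh <- min(h, t_end - t)
    k1 <- oracle_deriv(y, caf(t), p)
    k2 <- oracle_deriv(y + hh / 2 * k1, caf(t + hh / 2), p)
    k3 <- oracle_deriv(y + hh / 2 * k2, caf(t + hh / 2), p)
    k4 <- oracle_deriv(y + hh * k3, caf(t + hh), p)
    y_new <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    next_i <- record(next_i, t, y, t + hh, y_new)
    t <- t + hh
    y <- y_new
  }
  colnames(out) <- c("depot", "nrp", "rrp", "rrp_ca", "rrp_ca2", "rrp_ca3",
                     "fused", "f")
  out
}

# Quasi-steady occupancies by building the linear system numerically from
# oracle_deriv (columns probed with unit vectors; the system is linear in
# the six non-fused pools at fixed Ca2+ and fixed sensor fraction).
oracle_steady_state <- function(ca, p) {
  f <- ca^p$n / (p$K_D^p$n + ca^p$n)
  probe <- function(x6) {
    y <- c(x6, 0, f)
    oracle_deriv(y, ca, p)[1:5]
  }
  A <- vapply(1:6, function(j) probe(replace(numeric(6), j, 1)),
              numeric(5))
  M <- rbind(A, rep(1, 6))
  qr.solve(M, c(numeric(5), p$V_tot))
}
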