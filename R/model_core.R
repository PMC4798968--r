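#' Steady-state activation of the priming sensor
#'
#' Fraction of the cooperative priming sensor (PS) carrying its full
#' complement of n Ca2+ ions at equilibrium:
#' `f = ca^n / (K_D^n + ca^n)`.  This fraction scales the forward rate of
#' the first priming step, `k1 = f * k1_max`.
#'
#' @param ca Ca2+ concentration, uM (vectorised, non-negative).
#' @param params a [model_parameters()] object.
#' @return Activated fraction in `[0, 1]`, same length as `ca`.
#' @export
#' @examples
#' ps_steady_fraction(0.407, default_parameters("control"))  # 0.5 at K_D
ps_steady_fraction <- function(ca, params) {
  if (any(!is.finite(ca)) || any(ca < 0)) {
    abort("`ca` must be non-negative", class = "primekin_input_error")
  }
  can <- ca^params$n
  can / (params$K_D^params$n + can)
}

#' Priming-sensor occupancy along a Ca2+ trace
#'
#' Integrates the PS Ca2+-binding kinetics
#' `df/dt = k_on * (1 - f) * ca(t)^n - k_off * f`
#' (occupancies expressed as a fraction of total sensor, `k_off = k_on *
#' K_D^n`), with Ca2+ linearly interpolated between the trace samples.
#' For constant Ca2+ the solution relaxes exponentially with rate
#' `k_on * ca^n + k_off` towards [ps_steady_fraction()].
#'
#' @param trace a [ca_trace()].
#' @param params a [model_parameters()] object.
#' @param f0 initial bound fraction in `[0, 1]`; defaults to the steady-state
#'   fraction at the first sample's Ca2+.
#' @param times output times, s; defaults to the trace's sample times.
#' @return A tibble with columns `time_s` and `fraction`.
#' @export
ps_bound_fraction_ode <- function(trace, params, f0 = NULL, times = NULL) {
  stopifnot(inherits(trace, "ca_trace"))
  times <- times %||% trace$time_s
  caf <- approxfun(trace$time_s, trace$ca_um, rule = 2)
  if (is.null(f0)) f0 <- ps_steady_fraction(trace$ca_um[1], params)
  check_fraction(f0, "f0")
  rhs <- function(t, y, p) {
    ca_n <- caf(t)^p$n
    list(p$k_on * (1 - y[1]) * ca_n - p$k_off * y[1])
  }
  sol <- deSolve::ode(c(f = f0), times, rhs, params, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  tibble(time_s = sol[, "time"],
         fraction = pmin(1, pmax(0, sol[, "f"])))
}

#' Ca2+-dependent transition rates
#'
#' Evaluates the Ca2+-modulated rate constants of the two priming steps:
#' `k1 = ps_fraction * k1_max` for priming 1, and for the catalysed priming-2
#' step `k2 = k_20 + g * k_2cat`, `k_minus2 = k_minus20 + g * k_minus2cat`
#' with single-site catalyst activation `g = ca / (K_D_cat + ca)` and
#' `k_minus2cat = k_minus20 * k_2cat / k_20`.
#'
#' @param ca Ca2+ concentration, uM (vectorised).
#' @param ps_fraction activated priming-sensor fraction in `[0, 1]`.
#' @param params a [model_parameters()] object.
#' @return A tibble with columns `k1`, `k2`, `k_minus2` (s^-1).
#' @export
transition_rates <- function(ca, ps_fraction, params) {
  if (any(!is.finite(ca)) || any(ca < 0)) {
    abort("`ca` must be non-negative", class = "primekin_input_error")
  }
  check_fraction(ps_fraction, "ps_fraction")
  g <- ca / (params$K_D_cat + ca)
  tibble(
    k1 = ps_fraction * params$k1_max,
    k2 = params$k_20 + g * params$k_2cat,
    k_minus2 = params$k_minus20 + g * params$k_minus2cat
  )
}

pool_names <- function() {
  c("depot", "nrp", "rrp", "rrp_ca", "rrp_ca2", "rrp_ca3", "fused")
}

# Right-hand side of the full model: seven pool states plus the
# priming-sensor fraction, driven by ca(t).
model_rhs <- function(t, y, p, caf) {
  ca <- caf(t)
  f <- y[8]
  ca_n <- ca^p$n
  k1 <- f * p$k1_max
  g <- ca / (p$K_D_cat + ca)
  k2 <- p$k_20 + g * p$k_2cat
  km2 <- p$k_minus20 + g * p$k_minus2cat
  b <- p$k_3 * ca      # per-site fusion-sensor binding
  u <- p$k_minus3      # per-site unbinding
  d <- numeric(8)
  d[1] <- -k1 * y[1] + p$k_minus1 * y[2]
  d[2] <- k1 * y[1] - (p$k_minus1 + k2) * y[2] + km2 * y[3]
  d[3] <- k2 * y[2] - (km2 + 3 * b) * y[3] + u * y[4]
  d[4] <- 3 * b * y[3] - (u + 2 * b) * y[4] + 2 * u * y[5]
  d[5] <- 2 * b * y[4] - (2 * u + b) * y[5] + 3 * u * y[6]
  d[6] <- b * y[5] - (3 * u + p$k_4) * y[6]
  d[7] <- p$k_4 * y[6]
  d[8] <- p$k_on * (1 - f) * ca_n - p$k_off * f
  list(d)
}

# Clip solver round-off below zero; anything materially negative is a
# numerical failure, not round-off.
guard_negative <- function(m, V_tot) {
  lo <- min(m)
  if (lo < -1e-9 * V_tot) {
    abort(sprintf("negative pool occupancy %.3g fF exceeds round-off guard",
                  lo), class = "primekin_numerical_error")
  }
  pmax(m, 0)
}

#' Pre-flash steady state of the pool system
#'
#' Solves the quasi-steady occupancies used to initialise a simulation: the
#' balance equations of Depot, NRP, RRP, RRPCa and RRPCa2 are set to zero
#' together with mass conservation over the six non-fused states (the RRPCa3
#' balance is deliberately not included; at sub-micromolar pre-flash Ca2+ the
#' fusion leak through RRPCa3 is negligible).  Rates are evaluated at the
#' steady-state priming-sensor fraction.  The system is linear in the six
#' occupancies and is solved directly.
#'
#' @param ca_pre pre-flash Ca2+ concentration, uM.
#' @param params a [model_parameters()] object.
#' @param tol residual tolerance (fF) for each zeroed balance equation,
#'   relative to `V_tot`.
#' @return A one-row tibble with the seven pool occupancies (fF; `fused` is
#'   0) and `ps_bound_fraction`.
#' @export
steady_state <- function(ca_pre, params, tol = 1e-9) {
  if (!is.finite(ca_pre) || ca_pre < 0) {
    abort("`ca_pre` must be non-negative", class = "primekin_input_error")
  }
  f <- ps_steady_fraction(ca_pre, params)
  r <- transition_rates(ca_pre, f, params)
  b <- params$k_3 * ca_pre
  u <- params$k_minus3
  A <- rbind(
    c(-r$k1, params$k_minus1, 0, 0, 0, 0),
    c(r$k1, -(params$k_minus1 + r$k2), r$k_minus2, 0, 0, 0),
    c(0, r$k2, -(r$k_minus2 + 3 * b), u, 0, 0),
    c(0, 0, 3 * b, -(u + 2 * b), 2 * u, 0),
    c(0, 0, 0, 2 * b, -(2 * u + b), 3 * u),
    c(1, 1, 1, 1, 1, 1)
  )
  rhs <- c(0, 0, 0, 0, 0, params$V_tot)
  x <- tryCatch(solve(A, rhs), error = function(e) {
    abort(paste0("steady-state solve failed: ", conditionMessage(e)),
          class = "primekin_numerical_error")
  })
  resid <- A[1:5, , drop = FALSE] %*% x
  if (max(abs(resid)) > tol * params$V_tot) {
    abort(sprintf("steady-state residual %.3g exceeds tolerance",
                  max(abs(resid))), class = "primekin_numerical_error")
  }
  x <- guard_negative(x, params$V_tot)
  out <- tibble(depot = x[1], nrp = x[2], rrp = x[3], rrp_ca = x[4],
                rrp_ca2 = x[5], rrp_ca3 = x[6], fused = 0,
                ps_bound_fraction = f)
  out
}

#' Simulate a flash-photolysis capacitance response
#'
#' Forward-simulates the full model along a measured or synthetic Ca2+
#' trace.  Pools are initialised at the [steady_state()] of the mean
#' pre-flash Ca2+ (samples before the trace's flash time), then the seven
#' pool equations are integrated together with the priming-sensor equation
#' using a stiff-capable variable-step solver (the rates span more than four
#' orders of magnitude, from `k1 ~ 1e-2` to `k_4 ~ 1.45e3` s^-1).  Ca2+ is
#' interpolated piecewise-linearly between trace samples.  The predicted
#' capacitance change is the fused pool: `dcm_ff(t) = fused(t)`.
#'
#' @param trace a [ca_trace()]; the flash time attribute separates the
#'   pre-flash segment (used for initialisation) from the response.
#' @param params a [model_parameters()] object.
#' @param times output times, s; defaults to the trace's sample times.
#' @param rtol,atol solver tolerances (relative; absolute, fF).
#' @return An object of class `flash_simulation`: a list with `cm` (a
#'   [cm_trace()] of the simulated capacitance change), `pools` (tibble of
#'   all pool occupancies and the sensor fraction over time), and the
#'   `params` used.
#' @export
#' @examples
#' prot <- flash_protocol(pre_ca = 0.5, post_ca = 20)
#' sim <- simulate_flash(make_ca_trace(prot), default_parameters("control"))
#' head(sim$cm)
simulate_flash <- function(trace, params, times = NULL,
                           rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(trace, "ca_trace"), inherits(params, "model_parameters"))
  t_flash <- flash_time(trace)
  pre <- trace$ca_um[trace$time_s < t_flash]
  if (!length(pre)) {
    abort("trace has no pre-flash samples (time_s < flash time)",
          class = "primekin_input_error")
  }
  times <- times %||% trace$time_s
  if (min(times) < trace$time_s[1] - 1e-12 ||
      max(times) > tail(trace$time_s, 1) + 1e-12) {
    abort("requested output times are not covered by the Ca2+ trace",
          class = "primekin_input_error")
  }
  ca_pre <- mean(pre)
  ss <- steady_state(ca_pre, params)
  y0 <- c(unlist(ss[1, pool_names()]), f = ss$ps_bound_fraction)
  caf <- approxfun(trace$time_s, trace$ca_um, rule = 2)
  sol <- tryCatch(
    deSolve::ode(y0, times, model_rhs, params, caf = caf,
                 method = "lsoda", rtol = rtol, atol = atol),
    warning = function(w) {
      abort(paste0("ODE solver failed: ", conditionMessage(w)),
            class = "primekin_numerical_error")
    })
  pools <- guard_negative(unname(sol[, 2:8, drop = FALSE]), params$V_tot)
  colnames(pools) <- pool_names()
  pools_tbl <- as_tibble(as.data.frame(pools))
  pools_tbl$ps_bound_fraction <- pmin(1, pmax(0, sol[, 9]))
  pools_tbl <- dplyr::bind_cols(tibble(time_s = sol[, "time"]), pools_tbl)
  total <- rowSums(pools)
  if (max(abs(total - params$V_tot)) > 1e-6 * params$V_tot) {
    abort(sprintf("mass conservation violated by %.3g fF",
                  max(abs(total - params$V_tot))),
          class = "primekin_numerical_error")
  }
  structure(
    list(cm = cm_trace(sol[, "time"], cummax(pools_tbl$fused)),
         pools = pools_tbl,
         ca_pre = ca_pre,
         params = params),
    class = "flash_simulation"
  )
}

#' @export
print.flash_simulation <- function(x, ...) {
  cat(sprintf(
    "<flash_simulation> %d time points, pre-flash Ca2+ %.3g uM, final dCm %.1f fF\n",
    nrow(x$cm), x$ca_pre, tail(x$cm$dcm_ff, 1)))
  invisible(x)
}
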