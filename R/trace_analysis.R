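#' Exponential burst decomposition of a capacitance trace
#'
#' Fits the post-flash capacitance change with two saturating exponentials
#' plus a line,
#' `dCm(t) = a_fast (1 - e^-(t-d)/tau_fast) + a_slow (1 - e^-(t-d)/tau_slow)
#' + r (t - d)` for `t >= d` (0 before), identifying the fast and slow
#' exocytotic bursts, the sustained release rate `r` and the exocytotic
#' delay `d` -- the time at which the fitted curve meets the pre-flash
#' capacitance level.  A third, slowest exponential is indistinguishable
#' from a line on a 4 s window, so the sustained component is fitted as
#' linear.  Components are labelled so that `tau_fast < tau_slow`.
#'
#' @param trace a [cm_trace()] covering at least 4 s after the flash.
#' @param t_flash flash time, s.
#' @param max_delay upper bound on the exocytotic delay, s.
#' @return An object of class `burst_fit` with fields `a_fast`, `tau_fast`,
#'   `a_slow`, `tau_slow` (fF; s), `sustained_rate` (fF/s), `delay` (s),
#'   plus `fit` (the `nls` object) and `data`.  A trace with no resolvable
#'   rise yields zero amplitudes and `degenerate = TRUE`.
#' @export
fit_burst_exponentials <- function(trace, t_flash = 0, max_delay = 0.05) {
  stopifnot(inherits(trace, "cm_trace"))
  post <- trace[trace$time_s >= t_flash, , drop = FALSE]
  if (!nrow(post) || max(post$time_s) - t_flash < 4) {
    abort("trace must cover at least 4 s after the flash",
          class = "primekin_input_error")
  }
  d <- tibble(t = post$time_s - t_flash, y = post$dcm_ff)
  burst_model <- function(t, a1, tau1, a2, tau2, r, delay) {
    s <- pmax(t - delay, 0)
    on <- as.numeric(t >= delay)
    on * (a1 * (1 - exp(-s / tau1)) + a2 * (1 - exp(-s / tau2)) + r * s)
  }
  rise <- interp_at(d$t, d$y, 0.5) # amplitude scale from the early burst
  tail_rate <- (interp_at(d$t, d$y, 4) - interp_at(d$t, d$y, 1.5)) / 2.5
  start <- list(a1 = max(0.6 * rise, 1e-3), tau1 = 0.02,
                a2 = max(0.4 * rise, 1e-3), tau2 = 0.2,
                r = max(tail_rate, 1e-3), delay = 1e-3)
  resid_fun <- function(par) {
    burst_model(d$t, par[1], par[2], par[3], par[4], par[5], par[6]) - d$y
  }
  # raw Levenberg-Marquardt: degenerate traces drive amplitudes to the zero
  # bound, where the Jacobian is legitimately rank-deficient
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start), fn = resid_fun,
      lower = c(a1 = 0, tau1 = 1e-4, a2 = 0, tau2 = 1e-3, r = 0, delay = 0),
      upper = c(a1 = Inf, tau1 = 2, a2 = Inf, tau2 = 20, r = Inf,
                delay = max_delay),
      control = minpack.lm::nls.lm.control(maxiter = 1000)
    ),
    error = function(e) {
      abort(paste0("burst fit failed to converge: ", conditionMessage(e)),
            class = "primekin_fit_error")
    })
  if (fit$info == 0) {
    abort(paste0("burst fit failed to converge: ", fit$message),
          class = "primekin_fit_error")
  }
  cf <- coef(fit)
  # order components by time constant
  if (cf["tau1"] > cf["tau2"]) {
    cf[c("a1", "tau1", "a2", "tau2")] <- cf[c("a2", "tau2", "a1", "tau1")]
  }
  degenerate <- (cf["a1"] + cf["a2"]) < 1e-6 * max(abs(d$y), 1)
  structure(list(
    a_fast = unname(cf["a1"]), tau_fast = unname(cf["tau1"]),
    a_slow = unname(cf["a2"]), tau_slow = unname(cf["tau2"]),
    sustained_rate = unname(cf["r"]), delay = unname(cf["delay"]),
    degenerate = degenerate, fit = fit, data = d
  ), class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<burst_fit> fast %.1f fF (tau %.3g s), slow %.1f fF (tau %.3g s), ",
           "sustained %.2f fF/s, delay %.2g ms%s\n"),
    x$a_fast, x$tau_fast, x$a_slow, x$tau_slow, x$sustained_rate,
    1e3 * x$delay, if (x$degenerate) " [no burst]" else ""))
  invisible(x)
}

#' @export
predict.burst_fit <- function(object, t, ...) {
  s <- pmax(t - object$delay, 0)
  as.numeric(t >= object$delay) *
    (object$a_fast * (1 - exp(-s / object$tau_fast)) +
       object$a_slow * (1 - exp(-s / object$tau_slow)) +
       object$sustained_rate * s)
}

#' Window-based burst and sustained-release metrics
#'
#' Model-free readout used when exponential components are not resolvable:
#' the exocytotic burst is the capacitance change 0.5 s after the flash, and
#' the sustained rate is the further change between 0.5 s and 4 s divided by
#' 3.5 s.  Values are read by linear interpolation.
#'
#' @param trace a [cm_trace()] covering `[0, 4]` s post-flash.
#' @param t_flash flash time, s.
#' @return A one-row tibble with `burst_ff` and `sustained_rate_ff_s`.
#' @export
window_burst_metrics <- function(trace, t_flash = 0) {
  stopifnot(inherits(trace, "cm_trace"))
  v <- interp_at(trace$time_s, trace$dcm_ff, t_flash + c(0.5, 4),
                 "capacitance trace")
  tibble(burst_ff = v[1], sustained_rate_ff_s = (v[2] - v[1]) / 3.5)
}

#' Pool readouts from a depolarisation train
#'
#' Bookkeeping of the capacitance staircase evoked by a train of
#' depolarisation pulses: the per-pulse capacitance jump is the level just
#' after minus just before each pulse window (medians over flanking windows
#' to suppress transients), the Immediately-Releasable Pool estimate is the
#' summed jump of the first six (10 ms) pulses, and the total RRP readout is
#' the capacitance at the end of the train relative to the pre-train
#' baseline.
#'
#' @param trace a [cm_trace()].
#' @param pulse_windows a two-column data frame (or matrix) of pulse start
#'   and end times, s, non-overlapping and increasing.
#' @param flank read-out window flanking each pulse, s.
#' @return A list with `per_pulse` (tibble: `pulse`, `dcm_ff`),
#'   `irp_estimate` (fF) and `rrp_total` (fF).
#' @export
train_pool_metrics <- function(trace, pulse_windows, flank = 5e-3) {
  stopifnot(inherits(trace, "cm_trace"))
  pw <- as.matrix(pulse_windows)
  if (ncol(pw) != 2 || any(pw[, 2] <= pw[, 1]) ||
      (nrow(pw) > 1 && any(pw[-1, 1] < pw[-nrow(pw), 2]))) {
    abort("pulse windows must be two-column, non-overlapping and increasing",
          class = "primekin_input_error")
  }
  if (min(pw) - flank < min(trace$time_s) ||
      max(pw) + flank > max(trace$time_s)) {
    abort("pulse windows (plus flanks) fall outside the trace",
          class = "primekin_input_error")
  }
  level <- function(lo, hi) {
    i <- trace$time_s >= lo & trace$time_s <= hi
    median(trace$dcm_ff[i])
  }
  per <- purrr::map_dbl(seq_len(nrow(pw)), function(k) {
    level(pw[k, 2], pw[k, 2] + flank) - level(pw[k, 1] - flank, pw[k, 1])
  })
  baseline <- level(pw[1, 1] - flank, pw[1, 1])
  final <- level(pw[nrow(pw), 2], pw[nrow(pw), 2] + flank)
  list(
    per_pulse = tibble(pulse = seq_len(nrow(pw)), dcm_ff = per),
    irp_estimate = sum(per[seq_len(min(6, length(per)))]),
    rrp_total = final - baseline
  )
}
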