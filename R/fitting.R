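#' Release fraction 30 ms after the flash
#'
#' The priming read-out of the Hill analysis: the capacitance increase 30 ms
#' after the uncaging stimulus divided by the increase after 3 s (traces
#' normalised to their amplitude after 3 s).  Both values are read by linear
#' interpolation at exactly 30 ms and 3 s post-flash.
#'
#' @param trace a [cm_trace()] covering at least `[0, 3]` s post-flash.
#' @param t_flash flash time, s.
#' @return The release fraction (dimensionless).
#' @export
release_fraction_30ms <- function(trace, t_flash = 0) {
  stopifnot(inherits(trace, "cm_trace"))
  vals <- interp_at(trace$time_s, trace$dcm_ff,
                    t_flash + c(0.03, 3), "capacitance trace")
  if (vals[2] <= 0) {
    abort("degenerate trace: capacitance change at 3 s is not positive",
          class = "primekin_degenerate_error")
  }
  vals[1] / vals[2]
}

#' Default pre-flash Ca2+ bin edges (uM)
#'
#' The binning scheme used when grouping cells by pre-flash Ca2+:
#' 250-350, 350-450, 450-550, 550-800, 800-1200 and 1200-1700 nM.
#' @return Numeric vector of bin edges, uM.
#' @export
default_ca_bins <- function() c(0.25, 0.35, 0.45, 0.55, 0.8, 1.2, 1.7)

#' Bin cells by pre-flash Ca2+ and average their capacitance traces
#'
#' Cells are assigned to the unique half-open bin `[lo, hi)` containing
#' their pre-flash Ca2+; cells outside all bins are dropped with a warning.
#' Within each bin the traces are resampled onto a common time grid (the
#' overlap of all member traces, at the first member's sampling step) and
#' averaged pointwise.
#'
#' @param cells a tibble with columns `pre_ca` (uM) and `cm` (list of
#'   [cm_trace()]), e.g. from [make_capacitance_dataset()].
#' @param bin_edges increasing bin edges, uM.
#' @return A tibble with one row per non-empty bin: `ca_lo`, `ca_hi`,
#'   `n_cells`, `mean_pre_ca` and the averaged trace in list-column `cm`.
#' @export
bin_and_average <- function(cells, bin_edges = default_ca_bins()) {
  stopifnot(is.data.frame(cells), all(c("pre_ca", "cm") %in% names(cells)))
  if (any(diff(bin_edges) <= 0)) {
    abort("`bin_edges` must be strictly increasing",
          class = "primekin_input_error")
  }
  bin <- findInterval(cells$pre_ca, bin_edges, rightmost.closed = FALSE)
  outside <- bin == 0 | bin == length(bin_edges)
  if (any(outside)) {
    warn(sprintf("%d cell(s) outside all Ca2+ bins were excluded",
                 sum(outside)))
  }
  keep <- cells[!outside, , drop = FALSE]
  bin <- bin[!outside]
  purrr::map_dfr(sort(unique(bin)), function(b) {
    members <- keep$cm[bin == b]
    t_lo <- max(purrr::map_dbl(members, ~ min(.x$time_s)))
    t_hi <- min(purrr::map_dbl(members, ~ max(.x$time_s)))
    grid <- seq(t_lo, t_hi, by = median(diff(members[[1]]$time_s)))
    avg <- rowMeans(vapply(members,
                           function(m) interp_at(m$time_s, m$dcm_ff, grid),
                           numeric(length(grid))))
    tibble(ca_lo = bin_edges[b], ca_hi = bin_edges[b + 1],
           n_cells = length(members),
           mean_pre_ca = mean(keep$pre_ca[bin == b]),
           cm = list(cm_trace(grid, avg)))
  })
}

#' Fit a Hill curve to release fractions
#'
#' Least-squares fit of `fraction = F_max * ca^n / (K_D^n + ca^n)` to
#' (pre-flash Ca2+, release fraction) points, estimating the priming
#' sensor's half-activation concentration `K_D`, cooperativity `n` and
#' asymptotic fraction `F_max`.  By construction the fitted curve passes
#' through `F_max / 2` at `ca = K_D`.
#'
#' @param points a data frame with columns `ca` (uM) and `fraction`.
#' @return An object of class `hill_fit` with elements `K_D`, `n`, `F_max`,
#'   the underlying `nls` fit and the data.  Supports [generics::tidy()],
#'   [generics::glance()] and `predict()`.
#' @export
#' @examples
#' pts <- tibble::tibble(ca = seq(0.25, 1.6, length.out = 12))
#' pts$fraction <- 0.6 * pts$ca^7.38 / (0.407^7.38 + pts$ca^7.38)
#' fit_hill(pts)
fit_hill <- function(points) {
  stopifnot(is.data.frame(points), all(c("ca", "fraction") %in% names(points)))
  if (nrow(points) < 4) {
    abort("need at least 4 points for a three-parameter Hill fit",
          class = "primekin_input_error")
  }
  if (sd(points$fraction) < 1e-12 || diff(range(points$ca)) < 1e-12) {
    abort("Hill fit unidentifiable: fractions (or Ca2+ values) are constant",
          class = "primekin_degenerate_error")
  }
  f_max0 <- max(points$fraction)
  half <- f_max0 / 2
  ord <- order(points$ca)
  kd0 <- approx(points$fraction[ord], points$ca[ord], xout = half,
                ties = "ordered")$y
  if (!is.finite(kd0)) kd0 <- median(points$ca)
  fit <- minpack.lm::nlsLM(
    fraction ~ F_max * ca^n / (K_D^n + ca^n),
    data = points,
    start = list(F_max = f_max0, K_D = kd0, n = 4),
    lower = c(F_max = 1e-6, K_D = 1e-6, n = 0.1),
    upper = c(F_max = 1.5, K_D = 100, n = 40),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  structure(list(K_D = unname(cf["K_D"]), n = unname(cf["n"]),
                 F_max = unname(cf["F_max"]), fit = fit,
                 data = as_tibble(points)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K_D = %.4g uM, n = %.3g, F_max = %.3g (%d points)\n",
              x$K_D, x$n, x$F_max, nrow(x$data)))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, ca, ...) {
  object$F_max * ca^object$n / (object$K_D^object$n + ca^object$n)
}

#' Piecewise-constant fit weights
#'
#' The weighting used when comparing simulated and measured capacitance:
#' weight 100 up to 80 ms post-flash, 10 from there to 1.2 s, 1 afterwards
#' (both boundaries closed on the left interval).  The heavier early weights
#' compensate for the fixed sampling rate putting most points on the slow
#' components.
#'
#' @param t time relative to the flash, s (vectorised).
#' @return Weights 100, 10 or 1.
#' @export
cost_weights <- function(t) {
  ifelse(t <= 0.08, 100, ifelse(t <= 1.2, 10, 1))
}

#' Weighted normalised cost between two capacitance traces
#'
#' Sum of weighted squared deviations between a data trace and a model
#' trace, normalised by the smaller of the two trace maxima (the choice that
#' yields the larger, i.e. more conservative, cost).  The model is linearly
#' interpolated onto the data's native time grid; weights follow
#' [cost_weights()] on time relative to the flash.
#'
#' @param model simulated [cm_trace()].
#' @param data measured [cm_trace()].
#' @param t_flash flash time, s.
#' @return Non-negative scalar cost.
#' @export
trace_cost <- function(model, data, t_flash = 0) {
  stopifnot(inherits(model, "cm_trace"), inherits(data, "cm_trace"))
  y_model <- interp_at(model$time_s, model$dcm_ff, data$time_s,
                       "model trace")
  m <- min(max(data$dcm_ff), max(y_model))
  if (m <= 0) {
    abort("degenerate traces: normalising maximum is not positive",
          class = "primekin_degenerate_error")
  }
  w <- cost_weights(data$time_s - t_flash)
  sum(w * (data$dcm_ff - y_model)^2) / m
}

#' Define a multi-condition fitting problem
#'
#' @param conditions a tibble (or data frame) with columns `label`, `ca`
#'   (list of [ca_trace()]) and `cm` (list of [cm_trace()]), one row per
#'   experimental condition.
#' @param init a [model_parameters()] object used as the starting point for
#'   every condition, or a named list of one per condition label.
#' @param free_shared names of parameters optimised as a single value shared
#'   across all conditions.
#' @param free_per_condition names of parameters optimised separately per
#'   condition.  Following the calibration design, `K_D` and `n` are fixed
#'   from the Hill analysis and are not free here by default.
#' @return A `fit_problem` list.
#' @export
fit_problem <- function(conditions, init,
                        free_shared = character(),
                        free_per_condition = c("k1_max")) {
  stopifnot(is.data.frame(conditions),
            all(c("label", "ca", "cm") %in% names(conditions)))
  if (inherits(init, "model_parameters")) {
    init <- setNames(rep(list(init), nrow(conditions)), conditions$label)
  }
  stopifnot(setequal(names(init), conditions$label))
  free <- c(free_shared, free_per_condition)
  bad <- setdiff(free, parameter_names())
  if (length(bad)) {
    abort(paste0("unknown free parameter(s): ", paste(bad, collapse = ", ")),
          class = "primekin_config_error")
  }
  if (length(intersect(free_shared, free_per_condition))) {
    abort("a parameter cannot be both shared and per-condition",
          class = "primekin_config_error")
  }
  structure(list(conditions = as_tibble(conditions), init = init,
                 free_shared = free_shared,
                 free_per_condition = free_per_condition),
            class = "fit_problem")
}

# Rebuild per-condition parameter sets from the log-parameter vector.
unpack_theta <- function(theta, problem) {
  labels <- problem$conditions$label
  ns <- length(problem$free_shared)
  np <- length(problem$free_per_condition)
  shared <- exp(theta[seq_len(ns)])
  names(shared) <- problem$free_shared
  out <- list()
  for (i in seq_along(labels)) {
    own <- exp(theta[ns + (i - 1) * np + seq_len(np)])
    names(own) <- problem$free_per_condition
    out[[labels[i]]] <- do.call(
      update_parameters,
      c(list(problem$init[[labels[i]]]), as.list(c(shared, own)))
    )
  }
  out
}

#' Fit the exocytosis model to capacitance data
#'
#' Minimises the summed [trace_cost()] over all conditions simultaneously
#' with a Nelder-Mead simplex, varying only the named free parameters
#' (shared parameters take one value across conditions, per-condition
#' parameters one value each).  Free parameters are log-transformed during
#' optimisation to enforce positivity.  The optimiser is restarted once
#' from its best vertex; if it fails to improve on the starting point the
#' initial parameters are returned with a warning flag.
#'
#' @param problem a [fit_problem()].
#' @param maxit maximum simplex iterations per start.
#' @param reltol relative convergence tolerance on the cost.
#' @return An object of class `model_fit`: `parameters` (named list of
#'   fitted [model_parameters()] per condition), `cost`, `initial_cost`,
#'   `evaluations`, `converged`, `improved`.
#' @export
fit_model <- function(problem, maxit = 2000, reltol = 1e-6) {
  stopifnot(inherits(problem, "fit_problem"))
  labels <- problem$conditions$label
  theta0 <- log(c(
    vapply(problem$free_shared,
           function(nm) problem$init[[1]][[nm]], numeric(1)),
    unlist(lapply(labels, function(l)
      vapply(problem$free_per_condition,
             function(nm) problem$init[[l]][[nm]], numeric(1))))
  ))
  objective <- function(theta) {
    par_sets <- tryCatch(unpack_theta(theta, problem),
                         error = function(e) NULL)
    if (is.null(par_sets)) return(1e12)
    total <- 0
    for (i in seq_along(labels)) {
      ca <- problem$conditions$ca[[i]]
      cm <- problem$conditions$cm[[i]]
      sim <- tryCatch(
        simulate_flash(ca, par_sets[[labels[i]]], times = cm$time_s),
        error = function(e) NULL)
      if (is.null(sim)) return(1e12)
      total <- total + trace_cost(sim$cm, cm, t_flash = flash_time(ca))
    }
    total
  }
  initial_cost <- objective(theta0)
  ctrl <- list(maxit = maxit, reltol = reltol)
  # optim warns that 1-D Nelder-Mead can be unreliable; the single-parameter
  # case is well-behaved here (smooth log-scale cost) and kept for
  # consistency with the multi-parameter path.
  opt <- suppressWarnings(
    optim(theta0, objective, method = "Nelder-Mead", control = ctrl))
  opt2 <- suppressWarnings(
    optim(opt$par, objective, method = "Nelder-Mead", control = ctrl))
  best <- if (opt2$value <= opt$value) opt2 else opt
  improved <- best$value <= initial_cost
  if (!improved) {
    warn("optimizer failed to improve on the initial parameters")
    best$par <- theta0
    best$value <- initial_cost
  }
  structure(list(
    parameters = unpack_theta(best$par, problem),
    cost = best$value,
    initial_cost = initial_cost,
    evaluations = unname(opt$counts["function"] + opt2$counts["function"]),
    converged = best$convergence == 0,
    improved = improved,
    problem = problem
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model_fit> %d condition(s), cost %.4g (initial %.4g), %d evaluations%s\n",
    length(x$parameters), x$cost, x$initial_cost, x$evaluations,
    if (!x$improved) " [did not improve]" else ""))
  invisible(x)
}
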