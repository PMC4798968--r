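#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model parameter set
#'
#' @param x a [model_parameters()] object.
#' @param ... unused.
#' @return A tibble with columns `parameter` and `value` (derived rates
#'   included).
#' @export
tidy.model_parameters <- function(x, ...) {
  nm <- c(parameter_names(), "k_off", "k_minus2cat")
  tibble(parameter = nm, value = vapply(nm, function(n) x[[n]], numeric(1)))
}

#' Tidy a Hill fit
#'
#' @param x a `hill_fit` from [fit_hill()].
#' @param ... unused.
#' @return A tibble with one row per parameter (`estimate` and, from the
#'   underlying `nls` fit, `std.error`).
#' @export
tidy.hill_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble(K_D = x$K_D, n = x$n, F_max = x$F_max,
         rss = sum(r^2), n_points = nrow(x$data))
}

#' Tidy a burst decomposition
#'
#' @param x a `burst_fit` from [fit_burst_exponentials()].
#' @param ... unused.
#' @return A tibble with one row per component (`a_fast`, `tau_fast`,
#'   `a_slow`, `tau_slow`, `sustained_rate`, `delay`).
#' @export
tidy.burst_fit <- function(x, ...) {
  tibble(
    term = c("a_fast", "tau_fast", "a_slow", "tau_slow", "sustained_rate",
             "delay"),
    estimate = c(x$a_fast, x$tau_fast, x$a_slow, x$tau_slow,
                 x$sustained_rate, x$delay))
}

#' @rdname tidy.burst_fit
#' @export
glance.burst_fit <- function(x, ...) {
  tibble(rss = sum(x$fit$fvec^2), degenerate = x$degenerate,
         n_points = nrow(x$data))
}

#' Tidy a multi-condition model fit
#'
#' @param x a `model_fit` from [fit_model()].
#' @param ... unused.
#' @return A tibble with columns `condition`, `parameter`, `value` for every
#'   parameter of every fitted condition.
#' @export
tidy.model_fit <- function(x, ...) {
  purrr::imap_dfr(x$parameters, function(p, label) {
    dplyr::mutate(tidy.model_parameters(p), condition = label,
                  .before = 1)
  })
}

#' @rdname tidy.model_fit
#' @export
glance.model_fit <- function(x, ...) {
  tibble(cost = x$cost, initial_cost = x$initial_cost,
         evaluations = x$evaluations, converged = x$converged,
         improved = x$improved)
}
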