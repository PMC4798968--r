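#' Plot a trace
#'
#' Quick line plots of the package's trace tibbles with unit-labelled axes.
#'
#' @param object a [ca_trace()], [cm_trace()] or [current_trace()].
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-traces
NULL

#' @rdname autoplot-traces
#' @exportS3Method ggplot2::autoplot
autoplot.ca_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$ca_um)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression("[Ca"^"2+"*"] ("*mu*"M)"))
}

#' @rdname autoplot-traces
#' @exportS3Method ggplot2::autoplot
autoplot.cm_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$dcm_ff)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta*"Cm (fF)"))
}

#' @rdname autoplot-traces
#' @exportS3Method ggplot2::autoplot
autoplot.current_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$i_pa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "current (pA)")
}

#' Plot a flash simulation
#'
#' Pool occupancies and simulated capacitance over time.
#'
#' @param object a `flash_simulation` from [simulate_flash()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.flash_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pools,
                              dplyr::all_of(pool_names()),
                              names_to = "pool", values_to = "occupancy_ff")
  long$pool <- factor(long$pool, levels = pool_names())
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$time_s, .data$occupancy_ff,
                               colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "occupancy (fF)", colour = "pool")
}

#' Plot a Hill fit
#'
#' Release-fraction points with the fitted Hill curve; the dashed guides
#' mark `K_D` and `F_max / 2`.
#'
#' @param object a `hill_fit` from [fit_hill()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(ca = seq(min(object$data$ca), max(object$data$ca),
                          length.out = 200))
  grid$fraction <- predict(object, grid$ca)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ca, .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$K_D, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$F_max / 2, linetype = "dashed") +
    ggplot2::labs(x = expression("pre-flash [Ca"^"2+"*"] ("*mu*"M)"),
                  y = "release fraction at 30 ms")
}

#' Plot a burst decomposition
#'
#' Data with the fitted two-exponential-plus-line curve overlaid.
#'
#' @param object a `burst_fit` from [fit_burst_exponentials()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.burst_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict(object, d$t)
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time after flash (s)", y = expression(Delta*"Cm (fF)"))
}
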