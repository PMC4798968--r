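ctrl <- default_parameters("control")

test_that("release fraction at 30 ms follows its analytic values", {
  t <- seq(0, 3.5, by = 0.001)
  expect_equal(release_fraction_30ms(cm_trace(t, rep(5, length(t)))), 1)
  expect_equal(release_fraction_30ms(cm_trace(t, 7 * t)), 0.01)
  tr <- cm_trace(t, 1 - exp(-t / 0.010))
  expect_equal(release_fraction_30ms(tr),
               (1 - exp(-3)) / (1 - exp(-300)), tolerance = 1e-6)
  expect_error(release_fraction_30ms(cm_trace(t, rep(0, length(t)))),
               class = "primekin_degenerate_error")
  expect_error(release_fraction_30ms(cm_trace(seq(0, 1, 0.01), seq(0, 1, 0.01))),
               class = "primekin_input_error")
})

test_that("cells are binned by pre-flash Ca2+ and averaged on a common grid", {
  t <- seq(-0.1, 3.5, by = 0.01)
  mk <- function(a) cm_trace(t, a * pmax(t, 0))
  cells <- tibble::tibble(
    pre_ca = c(0.30, 0.50, 0.52, 2.5),
    cm = list(mk(10), mk(20), mk(40), mk(5)))
  expect_warning(out <- bin_and_average(cells), "excluded")
  expect_equal(nrow(out), 2)
  # a 500 nM cell lands in the 450-550 nM bin
  expect_equal(out$ca_lo, c(0.25, 0.45))
  expect_equal(out$n_cells, c(1L, 2L))
  # single-member bin: average equals the cell's trace
  expect_equal(out$cm[[1]]$dcm_ff,
               approx(t, 10 * pmax(t, 0), out$cm[[1]]$time_s)$y)
  # two-member bin: pointwise mean
  expect_equal(out$cm[[2]]$dcm_ff,
               approx(t, 30 * pmax(t, 0), out$cm[[2]]$time_s)$y)
  # identical traces average to themselves
  same <- tibble::tibble(pre_ca = c(0.4, 0.4), cm = list(mk(10), mk(10)))
  avg <- bin_and_average(same)
  expect_equal(avg$cm[[1]]$dcm_ff,
               approx(t, 10 * pmax(t, 0), avg$cm[[1]]$time_s)$y)
})

test_that("Hill fit recovers noiseless parameters and honours its definition", {
  truth <- list(K_D = 0.407, n = 7.38, F_max = 0.6)
  pts <- tibble::tibble(ca = seq(0.25, 1.7, length.out = 14))
  pts$fraction <- truth$F_max * pts$ca^truth$n /
    (truth$K_D^truth$n + pts$ca^truth$n)
  fit <- fit_hill(pts)
  expect_equal(fit$K_D, truth$K_D, tolerance = 1e-4)
  expect_equal(fit$n, truth$n, tolerance = 1e-4)
  expect_equal(fit$F_max, truth$F_max, tolerance = 1e-4)
  # the fitted curve reaches half its asymptote at the fitted K_D
  expect_equal(predict(fit, fit$K_D), fit$F_max / 2)
  expect_error(fit_hill(dplyr::mutate(pts, fraction = 0.3)),
               class = "primekin_degenerate_error")
  expect_error(fit_hill(pts[1:3, ]), class = "primekin_input_error")
})

test_that("Hill fit is robust to multiplicative noise across seeded replicates", {
  truth <- list(K_D = 0.407, n = 7.38, F_max = 0.6)
  ca <- seq(0.25, 1.7, length.out = 14)
  clean <- truth$F_max * ca^truth$n / (truth$K_D^truth$n + ca^truth$n)
  ests <- withr::with_seed(7, purrr::map_dfr(1:50, function(i) {
    pts <- tibble::tibble(ca = ca,
                          fraction = clean * exp(rnorm(length(ca), 0, 0.05)))
    f <- fit_hill(pts)
    tibble::tibble(K_D = f$K_D, n = f$n)
  }))
  expect_lt(abs(median(ests$K_D) / truth$K_D - 1), 0.10)
  expect_lt(abs(median(ests$n) / truth$n - 1), 0.25)
})

test_that("trace cost is weighted, normalised and symmetric in the normaliser", {
  expect_equal(cost_weights(c(0.05, 0.08, 0.5, 1.2, 2)),
               c(100, 100, 10, 10, 1))
  t <- seq(0, 4, by = 0.01)
  a <- cm_trace(t, 100 * (1 - exp(-t / 0.3)))
  expect_equal(trace_cost(a, a), 0)
  b <- cm_trace(t, 80 * (1 - exp(-t / 0.3)))
  expect_equal(trace_cost(a, b), trace_cost(b, a))
  expect_gt(trace_cost(a, b), 0)
  zero <- cm_trace(t, rep(0, length(t)))
  expect_error(trace_cost(zero, zero), class = "primekin_degenerate_error")
})

test_that("model fit recovers per-condition priming rates from noiseless data", {
  p_a <- ctrl
  p_b <- update_parameters(ctrl, k1_max = 3 * ctrl$k1_max)
  prot <- flash_protocol(pre_ca = 0.5, post_ca = 20)
  ds_a <- make_capacitance_dataset(p_a, list(prot), noise_sd_ff = 0,
                                   sample_rate = 200)
  ds_b <- make_capacitance_dataset(p_b, list(prot), noise_sd_ff = 0,
                                   sample_rate = 200)
  conds <- tibble::tibble(label = c("a", "b"),
                          ca = c(ds_a$ca, ds_b$ca),
                          cm = c(ds_a$cm, ds_b$cm))
  init <- update_parameters(ctrl, k1_max = 2 * ctrl$k1_max)
  prob <- fit_problem(conds, init, free_per_condition = "k1_max")
  fit <- fit_model(prob, maxit = 400)
  expect_true(fit$improved)
  expect_lt(fit$cost, fit$initial_cost)
  expect_equal(fit$parameters$a$k1_max, p_a$k1_max, tolerance = 0.05)
  expect_equal(fit$parameters$b$k1_max, p_b$k1_max, tolerance = 0.05)
})

test_that("model fit started at the truth stays at the truth", {
  prot <- flash_protocol(pre_ca = 0.5, post_ca = 20)
  ds <- make_capacitance_dataset(ctrl, list(prot), noise_sd_ff = 0,
                                 sample_rate = 200)
  conds <- tibble::tibble(label = "a", ca = ds$ca, cm = ds$cm)
  prob <- fit_problem(conds, ctrl, free_per_condition = "k1_max")
  fit <- fit_model(prob, maxit = 100)
  expect_equal(fit$parameters$a$k1_max, ctrl$k1_max, tolerance = 1e-3)
  expect_lt(fit$cost, 1e-2)
})

test_that("fit problems validate their free-parameter sets", {
  prot <- flash_protocol(post_duration = 1)
  ds <- make_capacitance_dataset(ctrl, list(prot), noise_sd_ff = 0,
                                 sample_rate = 100)
  conds <- tibble::tibble(label = "a", ca = ds$ca, cm = ds$cm)
  expect_error(fit_problem(conds, ctrl, free_per_condition = "bogus"),
               class = "primekin_config_error")
  expect_error(fit_problem(conds, ctrl, free_shared = "k1_max",
                           free_per_condition = "k1_max"),
               class = "primekin_config_error")
})
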