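ctrl <- default_parameters("control")

test_that("priming-sensor steady-state fraction follows the Hill form", {
  expect_equal(ps_steady_fraction(0.407, ctrl), 0.5)
  expect_equal(ps_steady_fraction(0, ctrl), 0)
  # direct evaluation at twice the half-activation concentration
  expect_equal(ps_steady_fraction(2 * 0.407, ctrl),
               2^7.38 / (1 + 2^7.38), tolerance = 1e-10)
  ca <- seq(0, 3, by = 0.05)
  expect_true(all(diff(ps_steady_fraction(ca, ctrl)) >= 0))
  expect_error(ps_steady_fraction(-0.1, ctrl), class = "primekin_input_error")
})

test_that("sensor occupancy stays at equilibrium under constant Ca2+", {
  tr <- ca_trace(seq(0, 5, by = 0.01), rep(0.5, 501))
  f0 <- ps_steady_fraction(0.5, ctrl)
  sol <- ps_bound_fraction_ode(tr, ctrl, f0 = f0)
  expect_equal(sol$fraction, rep(f0, nrow(sol)), tolerance = 1e-7)
})

test_that("sensor relaxation to a Ca2+ step is exponential at the closed-form rate", {
  ca <- 10
  rate <- ctrl$k_on * ca^ctrl$n + ctrl$k_off
  expect_equal(rate, 0.215, tolerance = 2e-3)
  tr <- ca_trace(seq(0, 20, by = 0.01), rep(ca, 2001))
  sol <- ps_bound_fraction_ode(tr, ctrl, f0 = 0)
  f_inf <- ps_steady_fraction(ca, ctrl)
  expect_equal(sol$fraction,
               f_inf * (1 - exp(-rate * sol$time_s)), tolerance = 1e-5)
})

test_that("fully bound sensor decays at the off-rate when Ca2+ is removed", {
  p <- update_parameters(ctrl, K_D = 1, n = 1, k_on = 0.5) # k_off = 0.5 s^-1
  tr <- ca_trace(seq(0, 10, by = 0.05), rep(0, 201))
  sol <- ps_bound_fraction_ode(tr, p, f0 = 1)
  expect_equal(sol$fraction, exp(-p$k_off * sol$time_s), tolerance = 1e-6)
})

test_that("transition rates reproduce the catalyst algebra", {
  r <- transition_rates(138, 1, ctrl) # ca at the catalyst K_D
  expect_equal(r$k1, ctrl$k1_max)
  expect_equal(r$k2, 2.37e-2 + 0.5 * 39.5, tolerance = 1e-6)
  expect_equal(r$k_minus2, ctrl$k_minus20 + 0.5 * ctrl$k_minus2cat)
  r0 <- transition_rates(0, 0.3, ctrl)
  expect_equal(r0$k2, ctrl$k_20)
  expect_equal(r0$k_minus2, ctrl$k_minus20)
  # saturation limits
  rs <- transition_rates(1e6, 1, ctrl)
  expect_equal(rs$k2, ctrl$k_20 + ctrl$k_2cat, tolerance = 1e-3)
})

test_that("steady state solves the zeroed balance equations", {
  expect_equal(steady_state(0, ctrl)$depot, ctrl$V_tot)
  for (ca in c(0.1, 0.3, 0.5, 1, 1.6)) {
    ss <- steady_state(ca, ctrl)
    pools <- unlist(ss[1, c("depot", "nrp", "rrp", "rrp_ca", "rrp_ca2",
                            "rrp_ca3")])
    expect_equal(sum(pools), ctrl$V_tot, tolerance = 1e-10)
    oracle <- oracle_steady_state(ca, ctrl)
    expect_equal(unname(pools), unname(oracle), tolerance = 1e-8)
  }
})

test_that("simulation with zero Ca2+ throughout releases nothing", {
  tr <- ca_trace(seq(-0.2, 2, by = 0.01), rep(0, 221))
  sim <- simulate_flash(tr, ctrl)
  expect_equal(sim$cm$dcm_ff, rep(0, nrow(sim$cm)))
  expect_equal(sim$pools$depot, rep(ctrl$V_tot, nrow(sim$pools)))
})

test_that("simulated flash conserves mass and fuses monotonically", {
  for (cond in c("control", "ubmunc13_2_oe")) {
    p <- default_parameters(cond)
    tr <- make_ca_trace(flash_protocol(pre_ca = 0.4, post_ca = 20))
    sim <- simulate_flash(tr, p)
    total <- rowSums(sim$pools[, c("depot", "nrp", "rrp", "rrp_ca",
                                   "rrp_ca2", "rrp_ca3", "fused")])
    expect_lt(max(abs(total - p$V_tot)), 1e-6 * p$V_tot)
    expect_true(all(diff(sim$cm$dcm_ff) >= 0))
    expect_true(all(as.matrix(sim$pools[, 2:8]) >= 0))
  }
})

test_that("variable-step solution matches a fixed-step RK4 integrator", {
  tr <- make_ca_trace(flash_protocol(pre_ca = 0.4, post_ca = 20,
                                     pre_duration = 0.2, post_duration = 4),
                      sample_rate = 500)
  sim <- simulate_flash(tr, ctrl)
  ss <- steady_state(mean(tr$ca_um[tr$time_s < 0]), ctrl)
  y0 <- c(unlist(ss[1, c("depot", "nrp", "rrp", "rrp_ca", "rrp_ca2",
                         "rrp_ca3", "fused")]),
          ss$ps_bound_fraction)
  rk <- oracle_rk4(tr, ctrl, y0, h = 1e-4, times_out = tr$time_s)
  for (j in 1:7) {
    expect_lt(max(abs(as.matrix(sim$pools[, 1 + j]) - rk[, j])),
              1e-3 * ctrl$V_tot)
  }
  expect_lt(max(abs(sim$cm$dcm_ff - rk[, "fused"])) / max(rk[, "fused"]),
            1e-3)
})

test_that("a low-Ca2+ equilibrium initialisation stays put over one second", {
  tr <- ca_trace(seq(-0.2, 1, by = 0.01), rep(0.2, 121))
  sim <- simulate_flash(tr, ctrl)
  first <- as.matrix(sim$pools[1, 2:8])
  last <- as.matrix(sim$pools[nrow(sim$pools), 2:8])
  expect_lt(max(abs(last - first)), 0.01 * ctrl$V_tot)
})

test_that("simulation input errors are reported", {
  tr <- ca_trace(seq(0, 1, by = 0.01), rep(0.5, 101)) # no pre-flash samples
  expect_error(simulate_flash(tr, ctrl), class = "primekin_input_error")
  tr2 <- make_ca_trace(flash_protocol(post_duration = 1))
  expect_error(simulate_flash(tr2, ctrl, times = seq(0, 5, 0.1)),
               class = "primekin_input_error")
})
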