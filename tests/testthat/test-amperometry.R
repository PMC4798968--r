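test_that("the Gaussian filter attenuates by -3 dB at its cut-off", {
  fs <- 25000
  t <- seq(0, 0.5, by = 1 / fs)
  for (f0 in c(500, 1000, 2000)) {
    x <- sin(2 * pi * f0 * t)
    y <- gaussian_lowpass(x, fs, cutoff_hz = 1000)
    gain <- max(y[t > 0.1 & t < 0.4])
    expected <- exp(-log(2) / 2 * (f0 / 1000)^2)
    expect_equal(gain, expected, tolerance = 0.01)
  }
})

test_that("detection finds isolated events above threshold and nothing else", {
  fs <- 25000
  t <- seq(0, 2, by = 1 / fs)
  noise <- withr::with_seed(5, rnorm(length(t), 0, 0.3))
  expect_equal(nrow(detect_spikes(current_trace(t, noise))), 0)
  spike <- function(t0, peak) {
    s <- pmax(t - t0, 0)
    (1 - exp(-s / 5e-4)) * exp(-s / 3e-3) /
      max((1 - exp(-seq(0, 0.05, 1 / fs) / 5e-4)) *
            exp(-seq(0, 0.05, 1 / fs) / 3e-3)) * peak * (t >= t0)
  }
  one <- detect_spikes(current_trace(t, noise + spike(1, 30)))
  expect_equal(nrow(one), 1)
  expect_true(one$t_start < 1.001 && one$t_peak > 1 && one$t_peak < 1.01)
  none <- detect_spikes(current_trace(t, noise + spike(1, 4)))
  expect_equal(nrow(none), 0)
  # raising the threshold never increases the count
  mixed <- current_trace(t, noise + spike(0.5, 8) + spike(1.2, 30))
  n5 <- nrow(detect_spikes(mixed, threshold = 5))
  n10 <- nrow(detect_spikes(mixed, threshold = 10))
  n40 <- nrow(detect_spikes(mixed, threshold = 40))
  expect_true(n5 >= n10 && n10 >= n40)
  expect_equal(c(n5, n10, n40), c(2, 1, 0))
})

test_that("a triangular pulse is measured by its analytic area and half-width", {
  fs <- 25000
  t <- seq(0, 1, by = 1 / fs)
  base <- 0.010 # s
  y <- pmax(0, 20 * (1 - abs(t - 0.5) / (base / 2)))
  segs <- detect_spikes(current_trace(t, y))
  expect_equal(nrow(segs), 1)
  rec <- characterize_spike(attr(segs, "signal"), segs[1, ])
  # the 1 kHz filter rounds the sharp apex slightly; area is preserved
  expect_equal(rec$amplitude, 20, tolerance = 0.03)
  expect_equal(rec$charge, 0.1, tolerance = 0.02)      # pC: 20 pA * 10 ms / 2
  expect_equal(rec$t_half, 0.005, tolerance = 0.02)
  expect_false(rec$foot_present)
})

test_that("pre-spike feet are scored against the 2 pA threshold", {
  fs <- 25000
  t <- seq(0, 1, by = 1 / fs)
  shape <- function(foot_amp) {
    primekin:::amp_event_waveform(t, 0.5, 30, 5e-4, 3e-3, foot_amp, 4e-3)
  }
  with_foot <- analyze_spikes(current_trace(t, shape(3)))
  expect_equal(nrow(with_foot), 1)
  expect_true(with_foot$foot_present)
  expect_equal(with_foot$foot_amplitude, 3, tolerance = 0.15)
  expect_equal(with_foot$foot_duration, 4e-3, tolerance = 0.2)
  sub_threshold <- analyze_spikes(current_trace(t, shape(1.5)))
  expect_equal(nrow(sub_threshold), 1)
  expect_false(sub_threshold$foot_present)
  no_foot <- analyze_spikes(current_trace(
    t, primekin:::amp_event_waveform(t, 0.5, 30, 5e-4, 3e-3)))
  expect_false(no_foot$foot_present)
})

test_that("doubling the trace doubles amplitudes and charges only", {
  tr <- make_amperometric_trace(rate = 0.8, duration = 20, seed = 9,
                                min_spacing = 0.1)
  rec1 <- analyze_spikes(tr)
  rec2 <- analyze_spikes(current_trace(tr$time_s, 2 * tr$i_pa))
  expect_equal(nrow(rec1), nrow(rec2))
  expect_equal(rec2$amplitude, 2 * rec1$amplitude, tolerance = 0.05)
  expect_equal(rec2$charge, 2 * rec1$charge, tolerance = 0.05)
  expect_equal(rec2$t_half, rec1$t_half, tolerance = 0.05)
})

test_that("detected charges match the generator ground truth", {
  tr <- make_amperometric_trace(rate = 0.5, duration = 60, seed = 17,
                                baseline_noise_sd = 0.3, min_spacing = 0.1)
  truth <- attr(tr, "truth")
  rec <- analyze_spikes(tr)
  expect_equal(nrow(rec), nrow(truth))
  ord <- order(rec$t_peak)
  expect_equal(rec$charge[ord], truth$charge, tolerance = 0.02)
})

test_that("per-cell medians aggregate to means of cell medians", {
  one <- tibble::tibble(cell = 1, t_peak = 0.3, amplitude = 25, charge = 0.2,
                        duration = 0.01, t_half = 0.004, rise_time = 1e-3,
                        decay_time = 3e-3, foot_present = TRUE,
                        foot_amplitude = 3, foot_duration = 4e-3,
                        foot_charge = 0.012)
  two <- dplyr::mutate(one, cell = 2, amplitude = 35, foot_present = FALSE,
                       foot_amplitude = NA, foot_duration = NA,
                       foot_charge = NA)
  spikes <- dplyr::bind_rows(one, one, two)
  durations <- tibble::tibble(cell = c(1, 2, 3), duration_s = c(60, 50, 40))
  s <- summarize_amperometry(spikes, durations)
  expect_equal(s$per_cell$n_spikes, c(2L, 1L, 0L))
  expect_equal(s$per_cell$frequency, c(2 / 60, 1 / 50, 0))
  expect_equal(s$population$amplitude, mean(c(25, 35)))
  expect_equal(s$population$foot_fraction, mean(c(1, 0)))
  expect_equal(s$population$n_cells, 3)
  expect_error(summarize_amperometry(spikes,
                                     dplyr::mutate(durations, duration_s = 0)),
               class = "primekin_input_error")
})
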