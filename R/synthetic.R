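#' Flash-photolysis stimulation protocol
#'
#' Describes a synthetic Ca2+ uncaging experiment: a pre-flash plateau
#' (experimentally 0.25-1.7 uM, set by slow photolysis pulses), an
#' instantaneous step at the flash (t = 0) to tens of uM, and an optional
#' slow exponential relaxation of the post-flash level.
#'
#' @param pre_ca pre-flash Ca2+ plateau, uM.
#' @param post_ca Ca2+ immediately after the flash, uM.
#' @param pre_duration length of the simulated pre-flash segment, s.
#' @param post_duration length of the post-flash segment, s.
#' @param post_decay_tau time constant of the post-flash relaxation towards
#'   `pre_ca`, s, or `NULL` for a constant post-flash level.
#' @param noise_sd multiplicative-free Gaussian jitter added to the trace,
#'   uM (0 for a noiseless trace).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A `flash_protocol` list.
#' @export
flash_protocol <- function(pre_ca = 0.5, post_ca = 20, pre_duration = 0.5,
                           post_duration = 4, post_decay_tau = 5,
                           noise_sd = 0, seed = 1L) {
  check_positive(pre_ca, "pre_ca")
  check_positive(post_ca, "post_ca")
  check_positive(pre_duration, "pre_duration")
  check_positive(post_duration, "post_duration")
  if (!is.null(post_decay_tau)) check_positive(post_decay_tau, "post_decay_tau")
  structure(list(pre_ca = pre_ca, post_ca = post_ca,
                 pre_duration = pre_duration, post_duration = post_duration,
                 post_decay_tau = post_decay_tau, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "flash_protocol")
}

#' Synthetic Ca2+ uncaging trace
#'
#' Realises a [flash_protocol()] on a uniform grid: plateau at `pre_ca` for
#' negative times, step to `post_ca` at the flash (t = 0), optional
#' exponential relaxation, optional Gaussian jitter (clipped at 0 uM).
#' Deterministic for a given protocol (including its seed).
#'
#' @param protocol a [flash_protocol()].
#' @param sample_rate sampling rate, Hz.
#' @return A [ca_trace()] with flash at t = 0.
#' @export
make_ca_trace <- function(protocol, sample_rate = 500) {
  stopifnot(inherits(protocol, "flash_protocol"))
  dt <- 1 / sample_rate
  time_s <- seq(-protocol$pre_duration, protocol$post_duration, by = dt)
  ca <- ifelse(time_s < 0, protocol$pre_ca,
               if (is.null(protocol$post_decay_tau)) protocol$post_ca else
                 protocol$pre_ca + (protocol$post_ca - protocol$pre_ca) *
                   exp(-pmax(time_s, 0) / protocol$post_decay_tau))
  if (protocol$noise_sd > 0) {
    ca <- withr::with_seed(protocol$seed,
                           pmax(0, ca + rnorm(length(ca), 0, protocol$noise_sd)))
  }
  ca_trace(time_s, ca, flash_time = 0)
}

#' Synthetic capacitance dataset from the forward model
#'
#' Forward-simulates the exocytosis model for each protocol and emits
#' `n_cells` noisy "cells" (protocols recycled across cells), each the
#' noiseless simulated capacitance trace plus independent additive Gaussian
#' noise.  Ground truth (parameters, protocols, noise level) is attached as
#' the `"truth"` attribute so recovery tests can compare against it.
#'
#' @param params a [model_parameters()] object (shared ground truth).
#' @param protocols a list of [flash_protocol()]s.
#' @param noise_sd_ff capacitance noise standard deviation, fF.
#' @param n_cells number of cells to generate.
#' @param seed RNG seed for the capacitance noise.
#' @param sample_rate Ca2+/capacitance sampling rate, Hz.
#' @return A tibble with one row per cell: `cell`, `pre_ca` (uM), `ca`
#'   (list of [ca_trace()]), `cm` (list of noisy [cm_trace()]).
#' @export
make_capacitance_dataset <- function(params, protocols, noise_sd_ff = 5,
                                     n_cells = length(protocols), seed = 1L,
                                     sample_rate = 500) {
  stopifnot(inherits(params, "model_parameters"), length(protocols) >= 1)
  sims <- lapply(protocols, function(p) {
    tr <- make_ca_trace(p, sample_rate)
    list(ca = tr, sim = simulate_flash(tr, params))
  })
  idx <- rep_len(seq_along(protocols), n_cells)
  rows <- withr::with_seed(seed, lapply(seq_len(n_cells), function(i) {
    s <- sims[[idx[i]]]
    noisy <- s$sim$cm$dcm_ff +
      if (noise_sd_ff > 0) rnorm(nrow(s$sim$cm), 0, noise_sd_ff) else 0
    tibble(cell = i, pre_ca = s$sim$ca_pre,
           ca = list(s$ca),
           cm = list(cm_trace(s$sim$cm$time_s, noisy)))
  }))
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(params = params, protocols = protocols,
                             noise_sd_ff = noise_sd_ff, seed = seed)
  out
}

# Single amperometric event waveform on a time grid (pA): optional pre-spike
# foot plateau followed by a rise/decay biexponential, peak-normalised to
# `amplitude`.
amp_event_waveform <- function(time_s, t_onset, amplitude, rise_tau,
                               decay_tau, foot_amplitude = 0,
                               foot_duration = 0) {
  y <- numeric(length(time_s))
  t_spike <- t_onset + foot_duration
  if (foot_duration > 0 && foot_amplitude > 0) {
    i <- time_s >= t_onset & time_s < t_spike
    ramp_tau <- 2e-4
    y[i] <- foot_amplitude * (1 - exp(-(time_s[i] - t_onset) / ramp_tau))
  }
  j <- time_s >= t_spike
  s <- time_s[j] - t_spike
  shape <- (1 - exp(-s / rise_tau)) * exp(-s / decay_tau)
  peak <- max(shape)
  base <- if (foot_duration > 0 && foot_amplitude > 0) foot_amplitude else 0
  # spike rides on the decaying foot level
  y[j] <- pmax(shape / peak * amplitude, base * exp(-s / (2 * decay_tau)))
  y
}

#' Synthetic amperometric current trace
#'
#' Generates a carbon-fiber-like recording: spike onsets at
#' homogeneous-Poisson times (optionally thinned to enforce a minimum
#' spacing, for well-separated-event tests), each event a rise/decay
#' biexponential with an optional pre-spike foot plateau, on a Gaussian
#' noise baseline.  The ground-truth event list is attached as the
#' `"truth"` attribute (onset, amplitude, per-event charge integrated from
#' the noiseless waveform, foot fields).
#'
#' @param rate mean event rate, s^-1.
#' @param duration recording length, s.
#' @param amplitude_pa mean spike peak amplitude, pA (per-event amplitudes
#'   are drawn log-normally around this with 20% spread).
#' @param rise_tau,decay_tau event rise and decay time constants, s.
#' @param foot_probability probability that an event carries a foot.
#' @param foot_amplitude_pa foot plateau amplitude, pA.
#' @param foot_duration_s foot plateau duration, s.
#' @param baseline_noise_sd baseline Gaussian noise, pA.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param min_spacing minimum allowed onset spacing, s (0 = pure Poisson).
#' @return A [current_trace()] with a `"truth"` attribute (tibble of
#'   events).
#' @export
make_amperometric_trace <- function(rate, duration, amplitude_pa = 40,
                                    rise_tau = 5e-4, decay_tau = 3e-3,
                                    foot_probability = 0,
                                    foot_amplitude_pa = 3,
                                    foot_duration_s = 5e-3,
                                    baseline_noise_sd = 0.3, seed = 1L,
                                    fs = 25000, min_spacing = 0) {
  if (rate < 0) abort("`rate` must be >= 0", class = "primekin_input_error")
  check_positive(duration, "duration")
  time_s <- seq(0, duration, by = 1 / fs)
  withr::with_seed(seed, {
    # Poisson onsets, leaving margin for the event waveform itself
    onsets <- numeric(0)
    t <- 0.05
    while (rate > 0) {
      t <- t + rexp(1, rate)
      if (t > duration - 0.05) break
      if (!length(onsets) || t - tail(onsets, 1) >= min_spacing) {
        onsets <- c(onsets, t)
      }
    }
    n_ev <- length(onsets)
    amp <- amplitude_pa * exp(rnorm(n_ev, 0, 0.2))
    has_foot <- if (n_ev) runif(n_ev) < foot_probability else logical(0)
    i <- rnorm(length(time_s), 0, baseline_noise_sd)
    truth <- vector("list", n_ev)
    for (k in seq_len(n_ev)) {
      fa <- if (has_foot[k]) foot_amplitude_pa else 0
      fd <- if (has_foot[k]) foot_duration_s else 0
      w <- amp_event_waveform(time_s, onsets[k], amp[k], rise_tau, decay_tau,
                              fa, fd)
      i <- i + w
      truth[[k]] <- tibble(
        t_onset = onsets[k], amplitude = amp[k],
        charge = trapz(time_s, w),
        foot = has_foot[k],
        foot_amplitude = fa, foot_duration = fd
      )
    }
    out <- current_trace(time_s, i)
    attr(out, "truth") <- if (n_ev) dplyr::bind_rows(truth) else
      tibble(t_onset = numeric(), amplitude = numeric(), charge = numeric(),
             foot = logical(), foot_amplitude = numeric(),
             foot_duration = numeric())
    out
  })
}

#' Synthetic vesicle-to-membrane distance sample
#'
#' Emulates 3D electron-tomography distance measurements within 100 nm of
#' the plasma membrane: a `proximal_fraction` of vesicles lies within 40 nm,
#' of which a `docked_fraction` is in physical contact (recorded as distance
#' 0); the remaining proximal vesicles are uniform on (4, 40) nm and the
#' non-proximal remainder uniform on (40, 100) nm.
#'
#' @param n number of vesicles.
#' @param docked_fraction fraction of membrane-proximal vesicles that are
#'   docked.
#' @param proximal_fraction fraction of all vesicles within 40 nm.
#' @param seed RNG seed.
#' @return A tibble with column `distance_nm`.
#' @export
make_distance_sample <- function(n, docked_fraction, proximal_fraction = 0.7,
                                 seed = 1L) {
  check_fraction(docked_fraction, "docked_fraction")
  check_fraction(proximal_fraction, "proximal_fraction")
  if (n == 0) return(tibble(distance_nm = numeric()))
  withr::with_seed(seed, {
    proximal <- runif(n) < proximal_fraction
    docked <- proximal & runif(n) < docked_fraction
    d <- numeric(n)
    d[docked] <- 0
    d[proximal & !docked] <- runif(sum(proximal & !docked), 4, 40)
    d[!proximal] <- runif(sum(!proximal), 40, 100)
    tibble(distance_nm = d)
  })
}
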