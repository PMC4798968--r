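#' Zero-phase Gaussian low-pass filter
#'
#' Off-line filtering applied to amperometric currents before detection:
#' convolution with a symmetric Gaussian kernel whose -3 dB amplitude
#' cut-off is `cutoff_hz` (kernel sigma `= sqrt(ln 2) / (2 pi f_c)`).
#' Edges are handled by reflection, so the filter is zero-phase and
#' length-preserving.
#'
#' @param x signal, pA.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz -3 dB cut-off frequency, Hz.
#' @return Filtered signal, same length as `x`.
#' @export
gaussian_lowpass <- function(x, fs, cutoff_hz = 1000) {
  sigma_s <- sqrt(log(2)) / (2 * pi * cutoff_hz)
  sigma <- sigma_s * fs
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  padded <- c(rev(x[seq_len(half) + 1]), x, rev(x[length(x) - seq_len(half)]))
  as.numeric(stats::filter(padded, k, sides = 2))[half + seq_along(x)]
}

# Baseline-subtracted, Gaussian-filtered detection signal.
amp_signal <- function(trace, cutoff_hz = 1000, baseline_window = 0.2) {
  fs <- attr(trace, "fs_hz")
  filt <- gaussian_lowpass(trace$i_pa, fs, cutoff_hz)
  k <- ceiling(baseline_window * fs)
  if (k %% 2 == 0) k <- k + 1
  baseline <- as.numeric(stats::runmed(filt, k, endrule = "median"))
  tibble(time_s = trace$time_s, filtered = filt, baseline = baseline,
         y = filt - baseline)
}

# Split a segment at pronounced valleys between peaks that both clear the
# detection threshold (valley below half the smaller peak).
split_segment <- function(y, i0, i1, threshold) {
  seg <- y[i0:i1]
  n <- length(seg)
  if (n < 5) return(matrix(c(i0, i1), ncol = 2))
  is_peak <- c(FALSE, seg[2:(n - 1)] > seg[1:(n - 2)] &
                 seg[2:(n - 1)] >= seg[3:n], FALSE) & seg >= threshold
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(matrix(c(i0, i1), ncol = 2))
  cuts <- integer(0)
  for (j in seq_len(length(peaks) - 1)) {
    between <- seq(peaks[j], peaks[j + 1])
    valley <- between[which.min(seg[between])]
    if (seg[valley] < 0.5 * min(seg[peaks[j]], seg[peaks[j + 1]])) {
      cuts <- c(cuts, valley)
    }
  }
  bounds <- c(1L, cuts, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  cbind(i0 + starts - 1L, i0 + ends - 1L)
}

#' Detect amperometric spikes
#'
#' Detection operates on the baseline-subtracted, Gaussian-filtered current:
#' contiguous above-baseline excursions whose filtered peak exceeds the
#' detection threshold become spike segments, with boundaries at the
#' baseline re-crossings.  Overlapping events within one excursion are
#' separated at local minima that fall below 50% of the smaller adjacent
#' peak.
#'
#' @param trace a [current_trace()].
#' @param threshold detection threshold above local baseline, pA.
#' @param cutoff_hz Gaussian filter cut-off, Hz.
#' @param baseline_window running-median baseline window, s.
#' @return A tibble of segments (`t_start`, `t_end`, `t_peak`, `peak_pa`,
#'   and index columns `i_start`, `i_end`) with the preprocessed signal
#'   attached as attribute `"signal"`.
#' @export
detect_spikes <- function(trace, threshold = 5, cutoff_hz = 1000,
                          baseline_window = 0.2) {
  stopifnot(inherits(trace, "current_trace"))
  sig <- amp_signal(trace, cutoff_hz, baseline_window)
  y <- sig$y
  above <- y > 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    if (max(y[starts[k]:ends[k]]) < threshold) next
    pieces <- split_segment(y, starts[k], ends[k], threshold)
    for (p in seq_len(nrow(pieces))) {
      i0 <- pieces[p, 1]; i1 <- pieces[p, 2]
      if (max(y[i0:i1]) < threshold) next
      ip <- i0 + which.max(y[i0:i1]) - 1L
      segs[[length(segs) + 1L]] <- tibble(
        i_start = i0, i_end = i1,
        t_start = sig$time_s[i0], t_end = sig$time_s[i1],
        t_peak = sig$time_s[ip], peak_pa = y[ip])
    }
  }
  out <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble(i_start = integer(), i_end = integer(), t_start = numeric(),
           t_end = numeric(), t_peak = numeric(), peak_pa = numeric())
  attr(out, "signal") <- sig
  out
}

# Interpolated time at which y crosses `level`, scanning outward from the
# peak index; returns the boundary time if the level is never crossed.
cross_time <- function(tt, y, i_peak, level, dir) {
  i <- i_peak
  repeat {
    j <- i + dir
    if (j < 1 || j > length(y)) return(tt[i])
    if (y[j] <= level) {
      frac <- (y[i] - level) / (y[i] - y[j])
      return(tt[i] + frac * (tt[j] - tt[i]))
    }
    i <- j
  }
}

#' Characterise one detected spike
#'
#' Measures the spike parameters on the preprocessed (filtered,
#' baseline-subtracted) signal within a detected segment: peak amplitude;
#' charge as the time-integral above baseline over the segment (pC);
#' half-width `t_half` at 50% of peak; duration between the 5%-of-peak
#' crossings; rise time between the 25% and 75% crossings of the rising
#' phase and decay time 75% to 25% on the falling phase.  A pre-spike foot
#' is scored when the current dwells above `foot_threshold` for at least
#' `min_foot_duration` before the main rise (the 25% crossing); foot
#' amplitude (mean), duration and charge are measured on that plateau.
#'
#' @param signal the preprocessed signal (attribute `"signal"` of
#'   [detect_spikes()]).
#' @param segment one row of the segment tibble from [detect_spikes()].
#' @param foot_threshold foot detection threshold, pA.
#' @param rise_levels fractional levels bounding the rise/decay times.
#' @param duration_level fractional level bounding the spike duration.
#' @param min_foot_duration minimum dwell above `foot_threshold` that
#'   qualifies as a foot, s.
#' @return A one-row tibble (the spike record).
#' @export
characterize_spike <- function(signal, segment, foot_threshold = 2,
                               rise_levels = c(0.25, 0.75),
                               duration_level = 0.05,
                               min_foot_duration = 1e-3) {
  i0 <- segment$i_start; i1 <- segment$i_end
  tt <- signal$time_s; y <- signal$y
  ip <- i0 + which.max(y[i0:i1]) - 1L
  amp <- y[ip]
  lo <- rise_levels[1] * amp; hi <- rise_levels[2] * amp
  t_rise_lo <- cross_time(tt, y, ip, lo, -1L)
  t_rise_hi <- cross_time(tt, y, ip, hi, -1L)
  t_fall_hi <- cross_time(tt, y, ip, hi, +1L)
  t_fall_lo <- cross_time(tt, y, ip, lo, +1L)
  t_dur_lo <- cross_time(tt, y, ip, duration_level * amp, -1L)
  t_dur_hi <- cross_time(tt, y, ip, duration_level * amp, +1L)
  t_half_lo <- cross_time(tt, y, ip, amp / 2, -1L)
  t_half_hi <- cross_time(tt, y, ip, amp / 2, +1L)
  charge <- trapz(tt[i0:i1], y[i0:i1])

  # foot: dwell above foot_threshold before the main rise (25% crossing)
  t_foot_start <- cross_time(tt, y, ip, foot_threshold, -1L)
  foot_dur <- t_rise_lo - t_foot_start
  foot_present <- amp >= 2 * foot_threshold &&
    is.finite(foot_dur) && foot_dur >= min_foot_duration
  if (foot_present) {
    fi <- tt >= t_foot_start & tt <= t_rise_lo
    foot_amp <- mean(y[fi])
    foot_charge <- trapz(tt[fi], y[fi])
  } else {
    foot_dur <- NA_real_; foot_amp <- NA_real_; foot_charge <- NA_real_
  }
  tibble(
    t_peak = tt[ip], amplitude = amp, charge = charge,
    duration = t_dur_hi - t_dur_lo, t_half = t_half_hi - t_half_lo,
    rise_time = t_rise_hi - t_rise_lo, decay_time = t_fall_lo - t_fall_hi,
    foot_present = foot_present, foot_amplitude = foot_amp,
    foot_duration = if (foot_present) foot_dur else NA_real_,
    foot_charge = foot_charge
  )
}

#' Detect and characterise all spikes in a current trace
#'
#' Convenience pipeline: [detect_spikes()] followed by
#' [characterize_spike()] on every segment.
#'
#' @inheritParams detect_spikes
#' @param ... passed on to [characterize_spike()].
#' @return A tibble with one spike record per row.
#' @export
analyze_spikes <- function(trace, threshold = 5, cutoff_hz = 1000,
                           baseline_window = 0.2, ...) {
  segs <- detect_spikes(trace, threshold, cutoff_hz, baseline_window)
  sig <- attr(segs, "signal")
  if (!nrow(segs)) {
    return(characterize_spike(
      tibble(time_s = 0, y = 0), tibble(i_start = 1L, i_end = 1L))[0, ])
  }
  purrr::map_dfr(seq_len(nrow(segs)), function(k)
    characterize_spike(sig, segs[k, , drop = FALSE], ...))
}

#' Per-cell median summaries of amperometric spikes
#'
#' Computes, for each cell, the median of every spike parameter over that
#' cell's spikes, the spike frequency (spikes per second of recording) and
#' the foot fraction; the population value of each parameter is the mean of
#' the cell medians.  Cells without spikes contribute only their (zero)
#' frequency.
#'
#' @param spikes a tibble of spike records with an added `cell` column.
#' @param durations a data frame with columns `cell` and `duration_s`.
#' @return A list with `per_cell` and `population` tibbles.
#' @export
summarize_amperometry <- function(spikes, durations) {
  stopifnot(is.data.frame(spikes), "cell" %in% names(spikes),
            all(c("cell", "duration_s") %in% names(durations)))
  if (any(durations$duration_s <= 0)) {
    abort("recording durations must be positive",
          class = "primekin_input_error")
  }
  params <- c("duration", "t_half", "amplitude", "charge", "rise_time",
              "decay_time", "foot_amplitude", "foot_duration", "foot_charge")
  per_cell <- durations |>
    dplyr::left_join(
      spikes |>
        dplyr::group_by(.data$cell) |>
        dplyr::summarise(
          n_spikes = dplyr::n(),
          foot_fraction = mean(.data$foot_present),
          dplyr::across(dplyr::all_of(params),
                        ~ median(.x, na.rm = TRUE))),
      by = "cell") |>
    dplyr::mutate(
      n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
      frequency = .data$n_spikes / .data$duration_s) |>
    as_tibble()
  with_spikes <- per_cell[per_cell$n_spikes > 0, , drop = FALSE]
  population <- dplyr::summarise(
    with_spikes,
    dplyr::across(dplyr::all_of(c(params, "foot_fraction")),
                  ~ mean(.x, na.rm = TRUE)))
  population$frequency <- mean(per_cell$frequency)
  population$n_cells <- nrow(per_cell)
  list(per_cell = per_cell, population = as_tibble(population))
}
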