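#' Linear-to-areal vesicle density conversion
#'
#' Converts the number of membrane-proximal vesicles per um of plasma
#' membrane length, counted in ultrathin sections of 0.05 um thickness, into
#' vesicles per um^2 of membrane area: `n_a = n_l / (d_v + 0.05)`.  The
#' section thickness plus the mean vesicle diameter is the effective depth
#' from which a section recruits vesicle profiles.
#'
#' @param n_l membrane-proximal vesicles per um membrane length (vectorised).
#' @param d_v mean vesicle diameter, um.
#' @return Vesicles per um^2 of plasma-membrane area.
#' @export
#' @examples
#' vesicles_per_membrane_area(0.984, 0.1627)
vesicles_per_membrane_area <- function(n_l, d_v) {
  if (any(!is.finite(n_l)) || any(n_l < 0)) {
    abort("`n_l` must be non-negative", class = "primekin_input_error")
  }
  check_positive(d_v, "d_v")
  n_l / (d_v + EM_SECTION_THICKNESS_UM)
}

#' Docked-pool size per cell
#'
#' Scales the areal density of membrane-proximal vesicles up to the whole
#' cell: `membrane_proximal = n_a * a_c` and
#' `docked = membrane_proximal * docked_fraction`, where `a_c` is the cell
#' surface area (given directly in um^2, or derived from the cell
#' capacitance at a specific membrane capacitance of 1 uF/cm^2, i.e.
#' 10 fF/um^2) and `docked_fraction` is the fraction of membrane-proximal
#' vesicles in physical contact with the membrane (from electron
#' tomography).  Linear in both `a_c` and `docked_fraction`.
#'
#' @param data a data frame with columns `n_l` (per um), `d_v` (um),
#'   `docked_fraction`, and either `a_c` (um^2) or `cm_ff` (cell
#'   capacitance, fF).  One row per genotype/condition.
#' @return The input with added columns `n_a` (per um^2),
#'   `membrane_proximal` and `docked` (vesicles per cell).
#' @export
#' @examples
#' tibble::tibble(
#'   genotype = c("control", "dko"),
#'   n_l = c(0.984, 1.150), d_v = c(0.1627, 0.1525),
#'   a_c = c(421.23, 442.26), docked_fraction = c(0.3397, 0.3443)
#' ) |> docked_pool_estimate()
docked_pool_estimate <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("n_l", "d_v", "docked_fraction") %in% names(data)))
  check_fraction(data$docked_fraction, "docked_fraction")
  a_c <- if ("a_c" %in% names(data)) data$a_c else {
    if (!"cm_ff" %in% names(data)) {
      abort("provide either `a_c` (um^2) or `cm_ff` (fF)",
            class = "primekin_input_error")
    }
    data$cm_ff / SPECIFIC_CAPACITANCE_FF_PER_UM2
  }
  check_positive(a_c, "a_c")
  data |>
    dplyr::mutate(
      n_a = vesicles_per_membrane_area(.data$n_l, .data$d_v),
      membrane_proximal = .data$n_a * a_c,
      docked = .data$membrane_proximal * .data$docked_fraction) |>
    as_tibble()
}

#' Single-vesicle capacitance and pool vesicle count
#'
#' Capacitance of one spherical vesicle of the given diameter at a specific
#' membrane capacitance of 1 uF/cm^2 (`pi d^2 * 10 fF/um^2`), and the
#' number of such vesicles accounted for by a capacitance pool.
#'
#' @param diameter_um vesicle diameter, um.
#' @param pool_ff pool capacitance, fF (optional).
#' @return A tibble with `capacitance_ff` and, when `pool_ff` is given,
#'   `n_vesicles`.
#' @export
#' @examples
#' vesicle_capacitance_and_count(0.170, pool_ff = 40)
vesicle_capacitance_and_count <- function(diameter_um, pool_ff = NULL) {
  check_positive(diameter_um, "diameter_um")
  cap <- pi * diameter_um^2 * SPECIFIC_CAPACITANCE_FF_PER_UM2
  out <- tibble(capacitance_ff = cap)
  if (!is.null(pool_ff)) out$n_vesicles <- pool_ff / cap
  out
}

#' Vesicle-to-membrane distance histograms
#'
#' Bins vesicle-to-membrane distances using the conventions of the two EM
#' modalities: 2D ultrathin sections use 40 nm bins over 0-2 um; 3D
#' electron tomography uses a first 0-4 nm bin (all physically docked
#' vesicles, recorded as contact, fall here) followed by 2 nm bins up to
#' 100 nm.  Bins are closed on the left, `[lo, hi)`.  Alongside the counts,
#' two summary percentages are derived: membrane-proximal vesicles
#' (< 40 nm) as a percentage of all vesicles < 100 nm, and docked vesicles
#' (first 3D bin) as a percentage of membrane-proximal ones.
#'
#' @param distances a data frame with column `distance_nm` (>= 0), e.g.
#'   from [make_distance_sample()], or a bare numeric vector.
#' @param mode `"3d"` (tomography bins) or `"2d"` (ultrathin-section bins).
#' @return A list with `histogram` (tibble: `bin_lo`, `bin_hi`, `count`),
#'   `proximal_pct` and (3D mode) `docked_pct`.
#' @export
distance_histograms <- function(distances, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  d <- if (is.data.frame(distances)) distances$distance_nm else distances
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("distances must be finite and non-negative",
          class = "primekin_input_error")
  }
  edges <- if (mode == "2d") seq(0, 2000, by = 40) else c(0, 4, seq(6, 100, by = 2))
  in_range <- d < max(edges)
  bin <- findInterval(d[in_range], edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  hist <- tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 count = counts)
  n_100 <- sum(d < 100)
  n_prox <- sum(d < 40)
  out <- list(
    histogram = hist,
    proximal_pct = if (n_100 > 0) 100 * n_prox / n_100 else NA_real_
  )
  if (mode == "3d") {
    out$docked_pct <- if (n_prox > 0) 100 * sum(d < 4) / n_prox else NA_real_
  }
  out
}
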