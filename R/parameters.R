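#' Construct a model parameter set
#'
#' Bundles the rate constants of the sequential-pool exocytosis model for one
#' experimental condition.  The model describes vesicle maturation
#' Depot -> NRP -> RRP (two priming steps), three sequential Ca2+-binding
#' steps on the fusion sensor (RRP -> RRPCa -> RRPCa2 -> RRPCa3) and fusion
#' into the F pool.  The forward rate of the first priming step is scaled by
#' the fraction of a cooperative priming sensor (PS) that carries its full
#' complement of n Ca2+ ions; the second priming step is accelerated by a
#' single-Ca2+ catalyst with half-activation `K_D_cat`.
#'
#' Two rates are derived rather than free: the PS off-rate
#' `k_off = k_on * K_D^n` (so that `K_D` is the half-activation Ca2+
#' concentration of the sensor) and the catalysed reverse priming-2 rate
#' `k_minus2cat = k_minus20 * k_2cat / k_20` (detailed-balance of the
#' catalyst cycle).
#'
#' @param V_tot total vesicle pool size, fF.
#' @param k_on priming-sensor Ca2+ on-rate, s^-1 uM^-n.
#' @param K_D priming-sensor half-activation Ca2+ concentration, uM.
#' @param n priming-sensor cooperativity (Hill coefficient).
#' @param k1_max asymptotic forward priming-1 rate, s^-1.
#' @param k_minus1 reverse priming-1 rate, s^-1.
#' @param k_20 basal forward priming-2 rate, s^-1.
#' @param k_2cat catalysed forward priming-2 increment, s^-1.
#' @param k_minus20 basal reverse priming-2 rate, s^-1.
#' @param K_D_cat half-activation Ca2+ concentration of the priming-2
#'   catalyst, uM.
#' @param k_3 per-site Ca2+ on-rate of the fusion sensor, s^-1 uM^-1.
#' @param k_minus3 per-site Ca2+ off-rate of the fusion sensor, s^-1.
#' @param k_4 fusion rate from the triply Ca2+-bound state, s^-1.
#' @param condition optional condition label carried through results.
#'
#' @return An object of class `model_parameters`: a named list of the
#'   thirteen rates plus the derived `k_off` and `k_minus2cat`.
#' @seealso [default_parameters()] for the parameter sets shipped with the
#'   package, [simulate_flash()] for the forward model.
#' @export
#' @examples
#' p <- default_parameters("control")
#' p$k_4
model_parameters <- function(V_tot, k_on, K_D, n, k1_max, k_minus1,
                             k_20, k_2cat, k_minus20, K_D_cat,
                             k_3, k_minus3, k_4, condition = NA_character_) {
  vals <- list(
    V_tot = V_tot, k_on = k_on, K_D = K_D, n = n, k1_max = k1_max,
    k_minus1 = k_minus1, k_20 = k_20, k_2cat = k_2cat,
    k_minus20 = k_minus20, K_D_cat = K_D_cat,
    k_3 = k_3, k_minus3 = k_minus3, k_4 = k_4
  )
  for (nm in names(vals)) check_positive(vals[[nm]], nm)
  vals$k_off <- vals$k_on * vals$K_D^vals$n
  vals$k_minus2cat <- vals$k_minus20 * vals$k_2cat / vals$k_20
  vals$condition <- condition
  structure(vals, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>",
      if (!is.na(x$condition)) paste0(" condition: ", x$condition), "\n",
      sep = "")
  print(tidy.model_parameters(x), n = Inf)
  invisible(x)
}

parameter_names <- function() {
  c("V_tot", "k_on", "K_D", "n", "k1_max", "k_minus1", "k_20", "k_2cat",
    "k_minus20", "K_D_cat", "k_3", "k_minus3", "k_4")
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named entries replaced and all derived
#' rates recomputed.
#'
#' @param params a [model_parameters()] object.
#' @param ... named parameter values to replace.
#' @return A new `model_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "model_parameters"))
  repl <- list(...)
  bad <- setdiff(names(repl), parameter_names())
  if (length(bad)) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")),
          class = "primekin_config_error")
  }
  vals <- unclass(params)[parameter_names()]
  vals[names(repl)] <- repl
  do.call(model_parameters, c(vals, list(condition = params$condition)))
}

#' Load a parameter set from a JSON file
#'
#' The file must map condition labels to objects holding all thirteen model
#' parameters.  The package ships its fitted defaults for four experimental
#' conditions; see [default_parameters()].
#'
#' @param path path to a JSON parameter file.
#' @param condition condition label to extract.
#' @return A [model_parameters()] object.
#' @export
load_parameters <- function(path, condition) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path),
          class = "primekin_config_error")
  }
  all <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!condition %in% names(all)) {
    abort(sprintf("unknown condition '%s'; file provides: %s", condition,
                  paste(names(all), collapse = ", ")),
          class = "primekin_config_error")
  }
  entry <- all[[condition]]
  missing <- setdiff(parameter_names(), names(entry))
  if (length(missing)) {
    abort(sprintf("condition '%s' is missing parameter(s): %s", condition,
                  paste(missing, collapse = ", ")),
          class = "primekin_config_error")
  }
  do.call(model_parameters,
          c(lapply(parameter_names(), function(nm) entry[[nm]]) |>
              setNames(parameter_names()),
            list(condition = condition)))
}

#' Shipped model parameter sets
#'
#' Returns the fitted parameter set for one of the four experimental
#' conditions the model was calibrated on: `"control"` (heterozygous
#' control cells), `"unc13b_ko"` (Unc13b knock-out), `"munc13_1_oe"`
#' (Munc13-1 over-expression in the double knock-out) and
#' `"ubmunc13_2_oe"` (ubMunc13-2 over-expression in the double knock-out).
#' The conditions share the sensor affinity (`K_D`, `n`), pool size and
#' reverse rates, and differ in `k_on`, `k1_max`, `k_20` and `k_2cat`.
#'
#' @param condition one of the four condition labels.
#' @return A [model_parameters()] object.
#' @export
#' @examples
#' default_parameters("ubmunc13_2_oe")$k1_max
default_parameters <- function(condition = c("control", "unc13b_ko",
                                             "munc13_1_oe", "ubmunc13_2_oe")) {
  condition <- match.arg(condition)
  path <- system.file("extdata", "model_parameters.json",
                      package = "primekin", mustWork = TRUE)
  load_parameters(path, condition)
}
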