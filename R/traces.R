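#' Trace constructors
#'
#' Time-series containers used throughout the package, all plain tibbles with
#' unit-bearing column names so that pipelines stay transparent:
#' * `ca_trace()`: intracellular Ca2+, columns `time_s`, `ca_um`;
#'   flash photolysis time is carried as the `flash_time` attribute
#'   (convention: flash at `t = 0`, pre-flash samples at negative times).
#' * `cm_trace()`: membrane-capacitance change relative to the pre-flash
#'   baseline, columns `time_s`, `dcm_ff`.
#' * `current_trace()`: amperometric current, columns `time_s`, `i_pa`;
#'   sampling must be uniform to within 1% jitter.
#'
#' @param time_s sample times, s, strictly increasing.
#' @param ca_um Ca2+ concentration, uM, non-negative.
#' @param flash_time time of the uncaging flash, s.
#' @param dcm_ff capacitance change, fF.
#' @param i_pa current, pA.
#' @return A tibble of subclass `ca_trace`, `cm_trace` or `current_trace`.
#' @name traces
NULL

check_time <- function(time_s, min_len = 2) {
  if (length(time_s) < min_len) {
    abort(sprintf("trace needs at least %d samples", min_len),
          class = "primekin_input_error")
  }
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0)) {
    abort("`time_s` must be finite and strictly increasing",
          class = "primekin_input_error")
  }
  invisible(time_s)
}

new_trace <- function(df, subclass) {
  structure(df, class = c(subclass, class(tibble())))
}

#' @rdname traces
#' @export
ca_trace <- function(time_s, ca_um, flash_time = 0) {
  check_time(time_s)
  if (any(!is.finite(ca_um)) || any(ca_um < 0)) {
    abort("`ca_um` must be finite and non-negative",
          class = "primekin_input_error")
  }
  out <- new_trace(tibble(time_s = time_s, ca_um = ca_um), "ca_trace")
  attr(out, "flash_time") <- flash_time
  out
}

#' @rdname traces
#' @export
cm_trace <- function(time_s, dcm_ff) {
  check_time(time_s)
  new_trace(tibble(time_s = time_s, dcm_ff = dcm_ff), "cm_trace")
}

#' @rdname traces
#' @export
current_trace <- function(time_s, i_pa) {
  check_time(time_s)
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 0.01 * median(dt)) {
    abort("current traces must be uniformly sampled (within 1% jitter)",
          class = "primekin_input_error")
  }
  out <- new_trace(tibble(time_s = time_s, i_pa = i_pa), "current_trace")
  attr(out, "fs_hz") <- 1 / median(dt)
  out
}

trace_value_col <- function(kind) {
  switch(kind, ca = "ca_um", cm = "dcm_ff", current = "i_pa",
         abort("kind must be one of 'ca', 'cm', 'current'",
               class = "primekin_input_error"))
}

#' Read a trace from delimited text
#'
#' Accepts comma- or tab-separated files with a header line.  Column names
#' fix the units: `time_s` plus `ca_um` (Ca2+ trace), `dcm_ff` (capacitance
#' trace) or `i_pa` (current trace).  Inferring units from magnitudes is
#' deliberately not attempted.
#'
#' @param path file path.
#' @param kind one of `"ca"`, `"cm"`, `"current"`.
#' @param flash_time flash time for Ca2+ traces, s.
#' @return The corresponding trace tibble (see [traces]).
#' @export
read_trace <- function(path, kind = c("ca", "cm", "current"), flash_time = 0) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "primekin_input_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, strip.white = TRUE)
  value <- trace_value_col(kind)
  missing <- setdiff(c("time_s", value), names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s (header was '%s')", path,
                  paste(missing, collapse = ", "), first),
          class = "primekin_parse_error")
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    abort(sprintf("%s: time stamps not strictly increasing at data line %d",
                  path, bad[1] + 1L),
          class = "primekin_parse_error")
  }
  switch(kind,
         ca = ca_trace(df$time_s, df[[value]], flash_time = flash_time),
         cm = cm_trace(df$time_s, df[[value]]),
         current = current_trace(df$time_s, df[[value]]))
}

#' Write a trace to delimited text
#'
#' Round-trips with [read_trace()] for the same delimiter.
#'
#' @param trace a trace tibble (see [traces]).
#' @param path output path.
#' @param sep field separator, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sep = ",") {
  utils::write.table(as.data.frame(trace), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flash time of a Ca2+ trace
#' @param trace a [ca_trace()].
#' @return The flash time, s.
#' @export
flash_time <- function(trace) {
  attr(trace, "flash_time") %||% 0
}
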