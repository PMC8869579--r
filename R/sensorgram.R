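#' Assemble a sensorgram from a time-ordered series of spectra
#'
#' For each spectrum in a series, extracts the minimum insertion loss within
#' a band and the phase of S21 at a fixed frequency, producing the two
#' standard sensor readouts as functions of time. Phase is unwrapped along
#' the series (temporally), so sensorgrams may legitimately run beyond
#' +/-180 degrees.
#'
#' @param spectra A list of `lw_spectrum` objects, or a tibble with columns
#'   `time_s` and `spectrum` (list-column) as produced by [synth_series()].
#'   Bare lists take timestamps from each spectrum's `time_s` attribute, or
#'   an index sequence when absent.
#' @param f0 Fixed frequency for phase tracking, Hz (must lie on the grid
#'   span).
#' @param band Band for the minimum-IL search, Hz (default: full grid).
#' @param gate Optional [gate_window()]; when given, each spectrum is
#'   time-gated before extraction (the usual workflow: filter, then read).
#' @return A tibble of class `lw_sensorgram` with columns `time_s`,
#'   `min_il_db`, `f_min_hz`, `phase_deg`.
#' @export
build_sensorgram <- function(spectra, f0, band = NULL, gate = NULL) {
  if (is.data.frame(spectra)) {
    stopifnot(all(c("time_s", "spectrum") %in% names(spectra)))
    times <- spectra$time_s
    specs <- spectra$spectrum
  } else {
    specs <- spectra
    times <- vapply(seq_along(specs), function(i) {
      attr(specs[[i]], "time_s") %||% as.numeric(i - 1)
    }, numeric(1))
  }
  if (length(specs) < 1) abort("need at least one spectrum")
  if (is.unsorted(times)) abort("timestamps must be monotone non-decreasing")
  rows <- map(seq_along(specs), function(i) {
    sp <- as_spectrum(specs[[i]])
    if (f0 < min(sp$frequency) || f0 > max(sp$frequency))
      abort(sprintf("f0 = %.4g Hz outside the spectrum grid", f0))
    if (!is.null(gate)) sp <- time_gate(sp, gate)
    m <- extract_min_il(sp, band)
    s <- interp_s21(sp, f0)
    tibble(time_s = times[i], min_il_db = m$il_db, f_min_hz = m$f_min_hz,
           phase_raw = Arg(s))
  })
  out <- list_rbind(rows)
  out$phase_deg <- unwrap_phase(out$phase_raw) * 180 / pi
  out$phase_raw <- NULL
  attr(out, "f0") <- f0
  class(out) <- c("lw_sensorgram", class(out))
  out
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps from a sequence of wrapped phases (radians) by keeping
#' each consecutive difference within (-pi, pi].
#'
#' @param phase Numeric vector of phases in radians.
#' @return Unwrapped phases in radians, same length.
#' @export
unwrap_phase <- function(phase) {
  if (length(phase) < 2) return(phase)
  d <- diff(phase)
  jumps <- -round(d / (2 * pi))
  phase + c(0, cumsum(jumps)) * 2 * pi
}
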