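#' Two-port spectra
#'
#' A spectrum is a tibble with a strictly increasing `frequency` column (Hz)
#' and a complex `s21` column; full two-port data adds `s11`, `s12`, `s22`.
#' Model-generated spectra may carry the complex in-plane wavenumber as a
#' `kx` column, which the triple-transit echo generator uses. Metadata
#' (reference impedance, timestamp, delay path) travel as attributes.
#'
#' @param frequency Frequency grid in Hz, strictly increasing.
#' @param s21 Complex forward transmission coefficient.
#' @param ... Further columns (e.g. `s11`, `s12`, `s22`, `kx`).
#' @param z0 Reference impedance in ohms.
#' @param time_s Optional acquisition timestamp in seconds.
#' @return A tibble of class `lw_spectrum`.
#' @export
two_port_spectrum <- function(frequency, s21, ..., z0 = 50, time_s = NULL) {
  if (is.unsorted(frequency, strictly = TRUE))
    abort("frequency grid must be strictly increasing")
  out <- tibble(frequency = as.numeric(frequency), s21 = as.complex(s21), ...)
  attr(out, "z0") <- z0
  attr(out, "time_s") <- time_s
  class(out) <- c("lw_spectrum", class(out))
  out
}

is_spectrum <- function(x) inherits(x, "lw_spectrum")

as_spectrum <- function(x, ...) {
  if (is_spectrum(x)) return(x)
  stopifnot(is.data.frame(x), all(c("frequency", "s21") %in% names(x)))
  extra <- x[setdiff(names(x), c("frequency", "s21"))]
  do.call(two_port_spectrum, c(list(frequency = x$frequency, s21 = x$s21),
                               as.list(extra), list(...)))
}

#' Insertion loss of a spectrum
#'
#' `|S21|` in dB (negative values = loss), the standard reading of a
#' delay-line transmission measurement.
#'
#' @param spectrum An `lw_spectrum`.
#' @return Numeric vector of dB values along the frequency grid.
#' @export
insertion_loss_db <- function(spectrum) db20(spectrum$s21)

#' Extract the minimum-insertion-loss point
#'
#' Finds the frequency of maximum `|S21|` (i.e. minimum loss) within a band.
#' Ties are broken toward the lower frequency.
#'
#' @param spectrum An `lw_spectrum` (or data frame with `frequency`, `s21`).
#' @param band Length-2 numeric, Hz; default is the full grid.
#' @return One-row tibble with `f_min_hz` and `il_db`.
#' @export
extract_min_il <- function(spectrum, band = NULL) {
  spectrum <- as_spectrum(spectrum)
  f <- spectrum$frequency
  band <- band %||% range(f)
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) abort("band contains no frequency points")
  mag <- abs(spectrum$s21[sel])
  i <- which.max(mag)  # first maximum = lowest-frequency tie
  tibble(f_min_hz = f[sel][i], il_db = db20(spectrum$s21[sel][i]))
}

#' @export
print.lw_spectrum <- function(x, ...) {
  cat(sprintf("<lw_spectrum> %d points, %.4g-%.4g MHz\n", nrow(x),
              min(x$frequency) / 1e6, max(x$frequency) / 1e6))
  NextMethod()
}

# linear interpolation of a complex spectrum at arbitrary frequencies
interp_s21 <- function(spectrum, f) {
  re <- approx(spectrum$frequency, Re(spectrum$s21), xout = f)$y
  im <- approx(spectrum$frequency, Im(spectrum$s21), xout = f)$y
  complex(real = re, imaginary = im)
}
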