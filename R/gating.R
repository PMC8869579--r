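#' Time gate window
#'
#' The time window retained by [time_gate()]: signal arriving between
#' `t_start` and `t_stop` (the direct acoustic transit) is kept; everything
#' else (electromagnetic feedthrough near t = 0, triple-transit echoes
#' later) is removed. The gate edges are cosine-tapered over a fraction of
#' the window length to limit ringing.
#'
#' @param t_start,t_stop Window bounds in seconds, `0 <= t_start < t_stop`.
#'   Defaults are the 0.2–1.9 us transit window of the reference device.
#' @param taper `"cosine"` (default) or `"rectangular"`.
#' @param taper_fraction Fraction of the window length used for each cosine
#'   edge ramp (default 0.05).
#' @return A list of class `lw_gate`.
#' @export
gate_window <- function(t_start = 0.2e-6, t_stop = 1.9e-6,
                        taper = c("cosine", "rectangular"),
                        taper_fraction = 0.05) {
  taper <- arg_match(taper)
  if (t_start < 0 || t_start >= t_stop)
    abort("need 0 <= t_start < t_stop")
  if (taper_fraction < 0 || taper_fraction > 0.5)
    abort("taper_fraction must be in [0, 0.5]")
  structure(list(t_start = t_start, t_stop = t_stop, taper = taper,
                 taper_fraction = taper_fraction), class = "lw_gate")
}

# Tukey (cosine-tapered rectangular) window of length n with total taper
# fraction a (a/2 ramp at each end)
tukey_window <- function(n, a) {
  if (a <= 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < a / 2
  hi <- x > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / a + 1)))
  w
}

# gate weights evaluated on a time grid
gate_weights <- function(t, window) {
  w <- as.numeric(t >= window$t_start & t <= window$t_stop)
  if (window$taper == "cosine" && window$taper_fraction > 0) {
    ramp <- window$taper_fraction * (window$t_stop - window$t_start)
    lo <- t >= window$t_start & t < window$t_start + ramp
    hi <- t > window$t_stop - ramp & t <= window$t_stop
    w[lo] <- 0.5 * (1 - cos(pi * (t[lo] - window$t_start) / ramp))
    w[hi] <- 0.5 * (1 - cos(pi * (window$t_stop - t[hi]) / ramp))
  }
  w
}

#' Time-domain gating of a two-port spectrum
#'
#' Band-limited time gating as used in vector-network-analyzer
#' post-processing: the measured band is cosine-tapered at its edges (Tukey
#' window, to control Gibbs ringing of the band-limited impulse response),
#' inverse-transformed to the time domain, multiplied by the gate window,
#' transformed back, and compensated for the band-edge taper across the
#' interior of the band. Gating removes signal arriving outside the window —
#' electromagnetic feedthrough and triple-transit echoes — while changing
#' the in-window response only marginally at mid-band.
#'
#' A non-uniform frequency grid is resampled internally by linear
#' interpolation of the real and imaginary parts.
#'
#' @param spectrum An `lw_spectrum`.
#' @param window An [gate_window()].
#' @param band_taper Total Tukey taper fraction applied across the band
#'   edges before inversion (default 0.1).
#' @param compensate Divide the gated spectrum by the band window where it
#'   exceeds `0.05`, restoring mid-band levels (default TRUE).
#' @return The gated `lw_spectrum` (gates `s21`, and `s12` when present;
#'   reflection columns pass through unchanged).
#' @export
time_gate <- function(spectrum, window = gate_window(), band_taper = 0.1,
                      compensate = TRUE) {
  spectrum <- as_spectrum(spectrum)
  stopifnot(inherits(window, "lw_gate"))
  f <- spectrum$frequency
  n <- length(f)
  if (n < 16) abort("need at least 16 frequency points to gate")
  df <- diff(f)
  uniform <- diff(range(df)) <= 1e-9 * mean(df)
  if (!uniform) {
    fu <- seq(min(f), max(f), length.out = n)
    s21 <- interp_s21(spectrum, fu)
    sp_u <- spectrum
    sp_u$frequency <- fu
    sp_u$s21 <- s21
    spectrum <- sp_u
    f <- fu
    df <- diff(f)
  }
  delta_f <- mean(df)
  t_max <- 1 / delta_f
  if (window$t_start >= t_max)
    abort(sprintf(
      "gate window starts beyond the resolvable time span (%.3g s)", t_max))
  t <- (seq_len(n) - 1) / (n * delta_f)
  g <- gate_weights(t, window)
  wband <- tukey_window(n, band_taper)
  apply_gate <- function(s) {
    x <- fft(s * wband, inverse = TRUE) / n
    y <- fft(x * g)
    if (compensate) {
      ok <- wband > 0.05
      y[ok] <- y[ok] / wband[ok]
    }
    y
  }
  spectrum$s21 <- apply_gate(spectrum$s21)
  if (!is.null(spectrum[["s12"]])) spectrum$s12 <- apply_gate(spectrum$s12)
  attr(spectrum, "gated") <- window
  spectrum
}

#' Impulse response of a spectrum
#'
#' Band-limited impulse response obtained by inverse transform of the
#' (Tukey-windowed) band, on the alias-free time grid `0 ... 1/df`. Useful
#' to locate the direct transit and the triple-transit echo before choosing
#' a gate window.
#'
#' @inheritParams time_gate
#' @return A tibble with `time_s` and complex `amplitude`.
#' @export
impulse_response <- function(spectrum, band_taper = 0.1) {
  spectrum <- as_spectrum(spectrum)
  n <- nrow(spectrum)
  delta_f <- mean(diff(spectrum$frequency))
  t <- (seq_len(n) - 1) / (n * delta_f)
  x <- fft(spectrum$s21 * tukey_window(n, band_taper), inverse = TRUE) / n
  tibble(time_s = t, amplitude = x)
}
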