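#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap vars
NULL

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: transmission
#' spectra (`|S21|` in dB versus frequency), viscosity sweeps (insertion
#' loss and phase versus viscosity), sensorgrams (both readouts versus
#' time), IDT responses (conversion loss versus frequency) and dispersion
#' curves (phase velocity versus normalized thickness).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name lovewave-autoplot
NULL

#' @rdname lovewave-autoplot
#' @export
autoplot.lw_spectrum <- function(object, ...) {
  d <- tibble(frequency_mhz = object$frequency / 1e6,
              il_db = db20(object$s21))
  ggplot(d, aes(x = .data$frequency_mhz, y = .data$il_db)) +
    geom_line() +
    labs(x = "Frequency (MHz)", y = "|S21| (dB)")
}

#' @rdname lovewave-autoplot
#' @export
autoplot.lw_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[c("eta_cP", "IL_dB", "phase_deg")],
    c("IL_dB", "phase_deg"), names_to = "observable", values_to = "value")
  ggplot(d, aes(x = .data$eta_cP, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(vars(.data$observable), scales = "free_y", ncol = 1) +
    labs(x = "Viscosity (cP)", y = NULL)
}

#' @rdname lovewave-autoplot
#' @export
autoplot.lw_sensorgram <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[c("time_s", "min_il_db", "phase_deg")],
    c("min_il_db", "phase_deg"), names_to = "observable", values_to = "value")
  ggplot(d, aes(x = .data$time_s, y = .data$value)) +
    geom_line() +
    facet_wrap(vars(.data$observable), scales = "free_y", ncol = 1) +
    labs(x = "Time (s)", y = NULL)
}

#' @rdname lovewave-autoplot
#' @export
autoplot.lw_idt_response <- function(object, ...) {
  d <- tibble(frequency_mhz = object$frequency / 1e6, cl_db = object$cl_db)
  ggplot(d, aes(x = .data$frequency_mhz, y = -.data$cl_db)) +
    geom_line() +
    labs(x = "Frequency (MHz)", y = "-Conversion loss (dB)")
}

#' @rdname lovewave-autoplot
#' @export
autoplot.lw_dispersion_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$z, y = .data$phase_velocity)) +
    geom_line() + geom_point() +
    labs(x = "z = h / wavelength", y = "Phase velocity (m/s)")
}
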