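#' Interdigital transducer and delay-line designs
#'
#' `idt_design()` records the IDT geometry: total electrode (finger) count,
#' acoustic wavelength set by the finger period, acoustic aperture, and
#' metallization ratio. Twelve fingers are read as six electrode pairs by
#' default (`n_pairs = n_fingers / 2`); pass `n_pairs` explicitly for the
#' other reading found in the literature.
#'
#' `delay_line_design()` combines two IDTs with the center-to-center delay
#' path, the substrate electrical constants and the source/load impedance.
#'
#' @param n_fingers Number of electrodes (>= 2).
#' @param wavelength Acoustic wavelength in metres (finger period).
#' @param aperture Acoustic aperture in metres.
#' @param metallization Metallization ratio in (0, 1).
#' @param n_pairs Number of finger pairs; default `n_fingers / 2`.
#' @return An `lw_idt` / `lw_delay_line` object.
#' @examples
#' idt <- idt_design()                      # the reference 30 MHz geometry
#' dl <- delay_line_design(idt, delay_path = 37 * 144e-6)
#' @export
idt_design <- function(n_fingers = 12, wavelength = 144e-6,
                       aperture = 21 * 144e-6, metallization = 0.5,
                       n_pairs = NULL) {
  if (n_fingers < 2) abort("an IDT needs at least 2 fingers")
  if (wavelength <= 0 || aperture <= 0) abort("wavelength and aperture must be positive")
  if (metallization <= 0 || metallization >= 1)
    abort("metallization ratio must be in (0, 1)")
  n_pairs <- n_pairs %||% (n_fingers / 2)
  structure(list(n_fingers = n_fingers, n_pairs = n_pairs,
                 wavelength = wavelength, aperture = aperture,
                 metallization = metallization),
            class = "lw_idt")
}

#' Substrate electrical constants for the cross-field model
#'
#' Electromechanical coupling coefficient `k2` (dimensionless), static
#' capacitance per finger pair per unit aperture `cs` (F/m), and free-surface
#' shear velocity `v0` (m/s). Defaults are literature values for LiNbO3
#' 36Y-X (K^2 about 0.16; Cs about 0.5 pF per pair per mm), with `v0` from
#' the substrate constants of the packaged material library.
#'
#' @param k2 Coupling coefficient, in (0, 0.35).
#' @param cs Capacitance per finger pair per unit aperture, F/m.
#' @param v0 Free-surface shear velocity, m/s.
#' @return A list of class `lw_electrical`.
#' @export
substrate_electrical <- function(k2 = 0.16, cs = 5e-10,
                                 v0 = sqrt(86.3e9 / 4650)) {
  if (k2 <= 0 || k2 >= 0.35) abort("k2 must be in (0, 0.35)")
  if (cs <= 0 || v0 <= 0) abort("cs and v0 must be positive")
  structure(list(k2 = k2, cs = cs, v0 = v0), class = "lw_electrical")
}

#' @rdname idt_design
#' @param input_idt,output_idt [idt_design()] objects.
#' @param delay_path Center-to-center IDT separation in metres.
#' @param electrical [substrate_electrical()] constants.
#' @param z0 Source/load impedance in ohms.
#' @param bidirectional_loss_db Additive loss per IDT accounting for the
#'   bidirectional radiation of an untuned IDT (3 dB each way by default;
#'   set to 0 to disable).
#' @export
delay_line_design <- function(input_idt = idt_design(),
                              output_idt = input_idt,
                              delay_path = 37 * 144e-6,
                              electrical = substrate_electrical(),
                              z0 = 50, bidirectional_loss_db = 3) {
  stopifnot(inherits(input_idt, "lw_idt"), inherits(output_idt, "lw_idt"),
            inherits(electrical, "lw_electrical"))
  if (delay_path <= 0) abort("delay_path must be positive")
  if (z0 <= 0) abort("z0 must be positive")
  structure(list(input_idt = input_idt, output_idt = output_idt,
                 delay_path = delay_path, electrical = electrical,
                 z0 = z0, bidirectional_loss_db = bidirectional_loss_db),
            class = "lw_delay_line")
}

#' Synchronous frequency of an IDT
#'
#' `f0 = v / lambda`: the frequency at which the acoustic wavelength under
#' the transducer matches the finger period.
#'
#' @param design An [idt_design()].
#' @param v Phase velocity under the IDT in m/s (free-surface substrate
#'   velocity for a bare launch region).
#' @return Frequency in Hz.
#' @examples
#' synchronous_frequency(idt_design(), sqrt(86.3e9 / 4650)) # ~29.9 MHz
#' @export
synchronous_frequency <- function(design, v) {
  stopifnot(inherits(design, "lw_idt"))
  if (v <= 0) abort("velocity must be positive")
  v / design$wavelength
}

#' Cross-field circuit response of an IDT
#'
#' Radiation conductance, acoustic susceptance and conversion loss of one
#' IDT in the cross-field equivalent-circuit model. With
#' `X = Np * pi * (f - f0) / f0`:
#' `Ga(f) = Ga0 * (sin X / X)^2` with `Ga0 = 8 K^2 f0 Cs W Np^2`,
#' `Ba(f) = Ga0 * (sin 2X - 2X) / (2 X^2)` (the Hilbert partner of Ga),
#' and static capacitance `C_T = Np Cs W`. Conversion loss into a resistive
#' source `R`:
#' `CL = -10 log10( 2 Ga R / ((1 + Ga R)^2 + ((Ba + omega C_T) R)^2) )`,
#' plus the bidirectionality term when enabled. Both `Ga` and `Ba` are
#' evaluated analytically at the removable singularity `f = f0`.
#'
#' @param design An [idt_design()].
#' @param electrical [substrate_electrical()] constants.
#' @param f_grid Frequencies in Hz (should cover `f0`; a diagnostic warning
#'   is raised otherwise).
#' @param z0 Source resistance in ohms.
#' @param bidirectional_loss_db Additive dB per transit (default 3).
#' @return A tibble of class `lw_idt_response` with columns `frequency`,
#'   `ga`, `ba`, `cl_db`; attributes `f0`, `ct`, `ga0`.
#' @examples
#' r <- idt_response(idt_design(), substrate_electrical(),
#'                   seq(20e6, 40e6, length.out = 401))
#' r[which.min(r$cl_db), ]
#' @export
idt_response <- function(design, electrical = substrate_electrical(),
                         f_grid, z0 = 50, bidirectional_loss_db = 3) {
  stopifnot(inherits(design, "lw_idt"), inherits(electrical, "lw_electrical"))
  if (any(f_grid <= 0)) abort("frequencies must be positive")
  f0 <- synchronous_frequency(design, electrical$v0)
  if (f0 < min(f_grid) || f0 > max(f_grid))
    warn(sprintf("synchronous frequency %.4g MHz lies outside the grid", f0 / 1e6))
  np <- design$n_pairs
  w <- design$aperture
  ga0 <- 8 * electrical$k2 * f0 * electrical$cs * w * np^2
  ct <- np * electrical$cs * w
  x <- np * pi * (f_grid - f0) / f0
  sinc <- ifelse(abs(x) < 1e-9, 1, sin(x) / x)
  ga <- ga0 * sinc^2
  ba <- ifelse(abs(x) < 1e-9, 0, ga0 * (sin(2 * x) - 2 * x) / (2 * x^2))
  btot <- ba + 2 * pi * f_grid * ct
  cl <- -10 * log10(2 * ga * z0 / ((1 + ga * z0)^2 + (btot * z0)^2)) +
    bidirectional_loss_db
  out <- tibble(frequency = f_grid, ga = ga, ba = ba, cl_db = cl)
  attr(out, "f0") <- f0
  attr(out, "ct") <- ct
  attr(out, "ga0") <- ga0
  class(out) <- c("lw_idt_response", class(out))
  out
}

#' Synthesize the delay-line S21 from the two component models
#'
#' Composes the transmission-line model (propagation loss and phase over the
#' delay path, from the guided mode's complex wavenumber) with the
#' cross-field conversion losses of the two IDTs:
#' `|S21|_dB = -(CL_in + CL_out + alpha(f) * L)` and
#' `arg S21 = -Re(k_x(f)) * L`. The dispersion problem is solved at
#' `n_nodes` frequencies across the grid (warm-starting each solve from its
#' neighbour) and the complex wavenumber is spline-interpolated in between.
#'
#' @param design A [delay_line_design()].
#' @param stack The [layer_stack()] of the delay path.
#' @param f_grid Frequencies in Hz.
#' @param n_nodes Number of dispersion-solve nodes (default 25, or fewer for
#'   short grids).
#' @return An `lw_spectrum` with a `kx` column (complex wavenumber used at
#'   each frequency).
#' @examples
#' \donttest{
#' dl <- delay_line_design()
#' sp <- delay_line_s21(dl, reference_stack(top = load_material("water_25C")),
#'                      seq(25e6, 35e6, length.out = 201))
#' extract_min_il(sp)
#' }
#' @export
delay_line_s21 <- function(design, stack, f_grid, n_nodes = 25) {
  stopifnot(inherits(design, "lw_delay_line"), inherits(stack, "lw_stack"))
  if (is.unsorted(f_grid, strictly = TRUE))
    abort("f_grid must be strictly increasing")
  kx <- dispersion_over_grid(stack, f_grid, n_nodes)
  l <- design$delay_path
  cl_in <- idt_response(design$input_idt, design$electrical, f_grid,
                        z0 = design$z0,
                        bidirectional_loss_db = design$bidirectional_loss_db)$cl_db
  cl_out <- idt_response(design$output_idt, design$electrical, f_grid,
                         z0 = design$z0,
                         bidirectional_loss_db = design$bidirectional_loss_db)$cl_db
  amp <- undb20(-(cl_in + cl_out)) * exp(Im(kx) * l)
  s21 <- amp * exp(-1i * Re(kx) * l)
  out <- two_port_spectrum(f_grid, s21, kx = kx, z0 = design$z0)
  attr(out, "delay_path") <- l
  attr(out, "design") <- design
  out
}

# Solve the dispersion problem on a coarse node grid and interpolate the
# complex wavenumber onto f_grid. Nodes are solved in order with Newton
# warm starts from the previous node.
dispersion_over_grid <- function(stack, f_grid, n_nodes = 25) {
  if (length(f_grid) <= n_nodes) {
    nodes <- f_grid
  } else {
    nodes <- seq(min(f_grid), max(f_grid), length.out = n_nodes)
  }
  kx_nodes <- complex(length(nodes))
  sol <- solve_dispersion(stack, nodes[1])
  kx_nodes[1] <- sol$k_x
  if (length(nodes) > 1) {
    for (i in 2:length(nodes)) {
      omega <- 2 * pi * nodes[i]
      # warm start: scale the previous root to the new frequency
      kx0 <- kx_nodes[i - 1] * nodes[i] / nodes[i - 1]
      fit <- newton_polish(stack, omega, kx0, plane = 0, tol = 1e-10)
      if (!fit$converged) {
        fit_sol <- solve_dispersion(stack, nodes[i])
        fit <- list(kx = fit_sol$k_x)
      }
      kx_nodes[i] <- fit$kx
    }
  }
  if (length(nodes) == length(f_grid)) return(kx_nodes)
  re <- spline(nodes, Re(kx_nodes), xout = f_grid)$y
  im <- spline(nodes, Im(kx_nodes), xout = f_grid)$y
  complex(real = re, imaginary = im)
}

#' Add a triple-transit echo to a spectrum
#'
#' The parasitic signal that reflects off both IDTs travels the delay path
#' three times, arriving at three times the main transit delay and causing
#' frequency ripple with period `1 / (2 * transit time)`. This fixture-grade
#' generator adds the echo term `r^2 * S21 * e^{-j 2 k_x L}` using the
#' spectrum's stored complex wavenumber (or a pure delay when only a transit
#' time is known).
#'
#' @param spectrum An `lw_spectrum`, ideally from [delay_line_s21()] (whose
#'   `kx` column and `delay_path` attribute are used).
#' @param r Amplitude reflection coefficient at each IDT, in `[0, 1)`.
#' @param transit_time Main transit time in seconds; required if the
#'   spectrum has no `kx` column.
#' @return The spectrum with the echo folded into `s21`.
#' @export
triple_transit <- function(spectrum, r, transit_time = NULL) {
  spectrum <- as_spectrum(spectrum)
  if (r < 0 || r >= 1) abort("reflection coefficient r must be in [0, 1)")
  if (r == 0) return(spectrum)
  if (!is.null(spectrum[["kx"]]) && !is.null(attr(spectrum, "delay_path"))) {
    extra <- exp(-1i * spectrum$kx * 2 * attr(spectrum, "delay_path"))
  } else {
    if (is.null(transit_time))
      abort("spectrum carries no wavenumber; supply transit_time")
    extra <- exp(-1i * 2 * pi * spectrum$frequency * 2 * transit_time)
  }
  spectrum$s21 <- spectrum$s21 * (1 + r^2 * extra)
  spectrum
}
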