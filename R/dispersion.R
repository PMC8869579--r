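# Dispersion solving: locate the guided-mode root on the lossless twin of
# the stack by a real scan over phase velocity, then polish the complex root
# of the full lossy stack by damped Newton iteration.

# velocity bracket for guided modes: (slowest finite-layer shear velocity,
# substrate shear velocity)
velocity_bracket <- function(stack) {
  v_sub <- shear_velocity(stack$substrate)
  v_layers <- vapply(stack$layers, function(l) shear_velocity(l$material),
                     numeric(1))
  v_layers <- v_layers[is.finite(v_layers)]
  if (length(v_layers) == 0)
    abort("no solid finite layer: nothing can guide a Love mode")
  v_lo <- min(v_layers)
  if (v_lo >= v_sub)
    abort(paste0("no guided mode: slowest layer shear velocity (",
                 round(v_lo), " m/s) is not below the substrate's (",
                 round(v_sub), " m/s)"))
  c(v_lo, v_sub)
}

# Im of the resonance function on the lossless stack, as a function of v.
# (All transverse impedances of a lossless stack are purely imaginary, so
# the resonance function is too; its imaginary part changes sign at a mode.)
lossless_scan <- function(stack_ll, omega, plane, n_scan = 400) {
  br <- velocity_bracket(stack_ll)
  v_lo <- br[1] * (1 + 1e-9); v_hi <- br[2] * (1 - 1e-12)
  # uniform grid plus geometric refinement toward the substrate velocity,
  # where thin-layer modes sit extremely close to the band edge
  v <- sort(unique(c(
    seq(v_lo, v_hi, length.out = n_scan),
    br[2] * (1 - 10^seq(-11, -1, length.out = 80))
  )), decreasing = TRUE)
  g <- Im(resonance_fn(stack_ll, omega, omega / v, plane))
  list(v = v, g = g)
}

# roots of the lossless resonance, ordered by decreasing phase velocity
# (mode 0 first); pole crossings are filtered by the relative residual
lossless_roots <- function(stack_ll, omega, plane, n_scan = 400) {
  sc <- lossless_scan(stack_ll, omega, plane, n_scan)
  v <- sc$v; g <- sc$g
  idx <- which(is.finite(g[-1]) & is.finite(g[-length(g)]) &
                 g[-1] * g[-length(g)] < 0)
  roots <- numeric(0)
  for (i in idx) {
    r <- tryCatch(
      uniroot(function(vi) Im(resonance_fn(stack_ll, omega, omega / vi, plane)),
              lower = min(v[i], v[i + 1]), upper = max(v[i], v[i + 1]),
              tol = .Machine$double.eps^0.9)$root,
      error = function(e) NA_real_)
    if (is.na(r)) next
    if (resonance_residual(stack_ll, omega, omega / r, plane) < 1e-6)
      roots <- c(roots, r)
  }
  sort(roots, decreasing = TRUE)
}

# damped Newton iteration on the complex resonance function
newton_polish <- function(stack, omega, kx0, plane, tol = 1e-8,
                          max_iter = 60) {
  kx <- as.complex(kx0)
  f <- resonance_fn(stack, omega, kx, plane)
  for (it in seq_len(max_iter)) {
    res <- resonance_residual(stack, omega, kx, plane)
    if (res < tol) return(list(kx = kx, residual = res, iterations = it - 1L,
                               converged = TRUE))
    dk <- max(abs(kx), 1) * 1e-7
    df <- (resonance_fn(stack, omega, kx + dk, plane) -
             resonance_fn(stack, omega, kx - dk, plane)) / (2 * dk)
    if (!is.finite(abs(df)) || abs(df) == 0) break
    step <- f / df
    # damping: shrink the step until the residual decreases
    lambda <- 1
    repeat {
      kx_new <- kx - lambda * step
      f_new <- resonance_fn(stack, omega, kx_new, plane)
      if (abs(f_new) < abs(f) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    if (abs(f_new) >= abs(f) && lambda < 1 / 64) break
    kx <- kx_new; f <- f_new
  }
  list(kx = kx, residual = resonance_residual(stack, omega, kx, plane),
       iterations = max_iter, converged = FALSE)
}

# Newton polish with loss continuation as a fallback: scale all layer / top
# viscosities from 0 to 1 in a few steps, tracking the root.
polish_with_continuation <- function(stack, omega, kx0, plane, tol) {
  direct <- newton_polish(stack, omega, kx0, plane, tol)
  if (direct$converged) return(direct)
  scale_stack <- function(s) {
    sc <- function(m) {
      if (!is.null(m$eta)) {
        if (m$kind == "newtonian_liquid")
          newtonian_liquid(m$name, m$rho, m$eta * s)
        else viscoelastic_solid(m$name, m$rho, m$mu, m$eta * s)
      } else m
    }
    st <- stack
    st$layers <- lapply(stack$layers, function(l) layer(sc(l$material), l$h))
    if (!is.null(stack$top$eta) && stack$top$eta > 0 && s == 0)
      st$top <- vacuum_medium()
    else if (!is.null(stack$top$eta))
      st$top <- newtonian_liquid(stack$top$name, stack$top$rho, stack$top$eta * s)
    st
  }
  kx <- as.complex(kx0)
  for (s in c(0.1, 0.25, 0.5, 0.75, 1)) {
    fit <- newton_polish(scale_stack(s), omega, kx, plane, tol)
    kx <- fit$kx
  }
  fit
}

#' Solve the transverse-resonance dispersion problem
#'
#' Finds the complex in-plane wavenumber `k_x` at which the impedances
#' looking up and down from the reference plane sum to zero — the guided
#' Love mode of the layered stack at frequency `f`. The real root is first
#' bracketed on the lossless twin of the stack by scanning phase velocity
#' between the slowest layer shear velocity and the substrate shear
#' velocity; losses (layer viscosity, liquid loading) are then switched on
#' and the root polished in the complex plane by damped Newton iteration.
#'
#' @param stack An [layer_stack()].
#' @param f Frequency in Hz (positive scalar).
#' @param mode Mode index; `0` (default) is the fundamental, the root with
#'   phase velocity closest below the substrate shear velocity.
#' @param plane Reference-plane interface index (see
#'   [surface_impedance_up()]); the root is independent of this choice.
#' @param tol Relative residual tolerance for convergence.
#' @param n_scan Number of points in the lossless bracketing scan.
#' @return An object of class `lw_dispersion`: frequency, complex `k_x`,
#'   phase velocity, attenuation in dB/m and dB/wavelength, solver
#'   diagnostics, and the per-medium transverse wavenumbers. Use [tidy()] /
#'   [glance()] to get tibbles.
#' @examples
#' \donttest{
#' sol <- solve_dispersion(reference_stack(top = load_material("water_25C")),
#'                         f = 30e6)
#' glance(sol)
#' }
#' @export
solve_dispersion <- function(stack, f, mode = 0L, plane = 0, tol = 1e-8,
                             n_scan = 400) {
  stopifnot(inherits(stack, "lw_stack"), length(f) == 1, f > 0)
  omega <- 2 * pi * f
  st_ll <- lossless_stack(stack)
  roots <- lossless_roots(st_ll, omega, plane, n_scan)
  if (length(roots) < mode + 1)
    abort(sprintf("no guided mode %d found at %.4g Hz (found %d root(s))",
                  mode, f, length(roots)))
  v0 <- roots[mode + 1]
  fit <- polish_with_continuation(stack, omega, omega / v0, plane, tol)
  if (!fit$converged)
    abort(sprintf(
      "dispersion solver did not converge at %.4g Hz (residual %.3g)",
      f, fit$residual))
  new_dispersion(stack, f, fit, mode, plane)
}

new_dispersion <- function(stack, f, fit, mode, plane) {
  omega <- 2 * pi * f
  kx <- fit$kx
  alpha_np <- -Im(kx)                       # Np/m, >= 0 for passive stacks
  media <- c(list(stack$substrate), lapply(stack$layers, `[[`, "material"),
             list(stack$top))
  half <- c(TRUE, rep(FALSE, length(stack$layers)), TRUE)
  ky <- map2(media, half, function(m, h) {
    if (m$kind == "vacuum") NA_complex_
    else transverse_wavenumber(m, omega, kx, half_space = h)
  })
  medium_labels <- c("substrate",
                     vapply(stack$layers, function(l) l$material$name,
                            character(1)),
                     stack$top$name)
  structure(list(
    frequency = f,
    k_x = kx,
    phase_velocity = omega / Re(kx),
    attenuation_db_per_m = NEPER_TO_DB * alpha_np,
    attenuation_db_per_wavelength = NEPER_TO_DB * alpha_np * 2 * pi / Re(kx),
    k_y = setNames(ky, medium_labels),
    residual = fit$residual,
    iterations = fit$iterations,
    mode = mode,
    plane = plane,
    stack = stack
  ), class = "lw_dispersion")
}

#' @export
print.lw_dispersion <- function(x, ...) {
  cat(sprintf("<lw_dispersion> mode %d at %.6g MHz\n", x$mode,
              x$frequency / 1e6))
  cat(sprintf("  phase velocity: %.6g m/s\n", x$phase_velocity))
  cat(sprintf("  attenuation:    %.6g dB/m (%.4g dB/wavelength)\n",
              x$attenuation_db_per_m, x$attenuation_db_per_wavelength))
  cat(sprintf("  residual:       %.3g\n", x$residual))
  invisible(x)
}

#' Tidiers for dispersion solutions
#'
#' `tidy()` returns one row per medium of the stack with its transverse
#' wavenumber and transverse decay length; `glance()` returns a one-row
#' summary of the solved mode (phase velocity, attenuation, solver
#' diagnostics).
#'
#' @param x An `lw_dispersion` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lw_dispersion <- function(x, ...) {
  ky <- x$k_y
  tibble(
    medium = names(ky),
    k_y = unlist(ky),
    # 1/e decay length of e^{-j ky y}: meaningful where Im(ky) < 0
    decay_length_m = ifelse(Im(unlist(ky)) < 0, -1 / Im(unlist(ky)), NA_real_)
  )
}

#' @rdname tidy.lw_dispersion
#' @export
glance.lw_dispersion <- function(x, ...) {
  tibble(
    frequency = x$frequency,
    phase_velocity = x$phase_velocity,
    attenuation_db_per_m = x$attenuation_db_per_m,
    attenuation_db_per_wavelength = x$attenuation_db_per_wavelength,
    k_x_re = Re(x$k_x), k_x_im = Im(x$k_x),
    residual = x$residual, iterations = x$iterations,
    mode = x$mode
  )
}

#' Shear-wave penetration depth into a Newtonian liquid
#'
#' The 1/e decay length of the shear disturbance a surface acoustic device
#' drives into a Newtonian liquid, `delta = sqrt(eta / (rho * pi * f))`. It
#' sets the probed zone above the sensor: about 100 nm in water at 30 MHz,
#' about 50 nm at 100 MHz — the design lever for reaching beyond the focal
#' adhesions of an adherent cell layer.
#'
#' @param viscosity_cp Liquid viscosity in centipoise.
#' @param density Liquid density in kg/m3.
#' @param f Frequency in Hz. All arguments vectorised.
#' @return Penetration depth in metres.
#' @examples
#' penetration_depth(1, 1000, 30e6)  # ~1.03e-7 m
#' @export
penetration_depth <- function(viscosity_cp, density, f) {
  if (any(viscosity_cp <= 0) || any(density <= 0) || any(f <= 0))
    abort("viscosity, density and frequency must be positive")
  sqrt(cp_to_pas(viscosity_cp) / (density * pi * f))
}

#' Dispersion curve versus normalized guiding-layer thickness
#'
#' Solves the fundamental mode across a grid of guiding-layer thicknesses
#' expressed as `z = h / lambda`, the standard design chart for choosing the
#' operating point of a Love-wave sensor: sensitivity to surface loading is
#' greatest where the phase velocity falls steeply with `z`.
#'
#' @param stack_fn Function mapping a guiding-layer thickness in metres to an
#'   [layer_stack()]; defaults to the reference device with vacuum on top.
#' @param z Vector of `h / lambda` values.
#' @param f Frequency in Hz.
#' @param wavelength Acoustic wavelength in metres used to convert `z` to a
#'   thickness.
#' @return A tibble of class `lw_dispersion_curve`: `z`, `h_m`,
#'   `phase_velocity`, `attenuation_db_per_m`.
#' @examples
#' \donttest{
#' dispersion_curve(z = c(0.02, 0.056, 0.1))
#' }
#' @export
dispersion_curve <- function(stack_fn = function(h) reference_stack(h_guiding = h),
                             z = seq(0.01, 0.2, by = 0.01),
                             f = 30e6, wavelength = 144e-6) {
  rows <- map(z, function(zi) {
    h <- zi * wavelength
    sol <- solve_dispersion(stack_fn(h), f)
    tibble(z = zi, h_m = h, phase_velocity = sol$phase_velocity,
           attenuation_db_per_m = sol$attenuation_db_per_m)
  })
  out <- list_rbind(rows)
  class(out) <- c("lw_dispersion_curve", class(out))
  out
}
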