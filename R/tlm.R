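# Transmission-line model of the layered shear waveguide.
#
# Conventions (asserted by the liquid-loading property test):
#   time factor e^{+j omega t}, propagation e^{-j k_x x};
#   medium wavenumber k_i on the Im(k) <= 0 branch (decaying);
#   transverse wavenumber k_y,i = sqrt(k_i^2 - k_x^2), for half-spaces on the
#   Im(k_y) <= 0 branch so the field decays away from the guide;
#   transverse-line characteristic impedance Z_i = Zc_i * k_y,i / k_i
#   (stress/particle-velocity ratio of the oblique SH decomposition);
#   line propagation constant gamma_y = j * k_y (purely imaginary when
#   lossless), which is what transform_impedance() feeds to tanh().

#' Impedance transformation through a transmission-line section
#'
#' The standard line formula
#' `Z = Zc (ZL + Zc tanh(g h)) / (Zc + ZL tanh(g h))`
#' mapping a load impedance through a section of thickness `h`. The third
#' argument is the section's propagation constant `g = j k_y`: purely
#' imaginary for a lossless section (where `tanh(j beta h) = j tan(beta h)`
#' recovers the familiar lossless form), complex with positive real part for
#' a lossy one (so the `h -> Inf` limit returns `Zc`, a matched half-space).
#'
#' @param z_char Characteristic impedance of the section (non-zero complex).
#' @param z_load Load impedance seen at the far end.
#' @param gamma_y Transverse propagation constant of the section (1/m),
#'   `j * k_y` in wavenumber terms.
#' @param h Section thickness in metres (>= 0; `h = 0` returns `z_load`).
#' @return Complex impedance at the near end.
#' @examples
#' transform_impedance(2e7 + 0i, 0i, 1i * pi / 4, 1) # j * Zc (quarter-ish line)
#' @export
transform_impedance <- function(z_char, z_load, gamma_y, h) {
  if (h < 0) abort("section thickness must be non-negative")
  if (any(abs(z_char) == 0)) abort("z_char must be non-zero")
  t <- tanh(gamma_y * h)
  num <- z_load + z_char * t
  den <- z_char + z_load * t
  scale <- abs(z_char) * (abs(z_load) + abs(z_char) * abs(t)) + abs(num)
  bad <- abs(den) < 1e-30 * pmax(scale, 1)
  if (any(bad)) {
    if (length(num) == 1)
      abort("resonant short: impedance transformation is singular here")
    # vectorized scans step over poles; mark them non-finite instead
    den[bad] <- 0
  }
  z_char * num / den
}

# transverse wavenumber of a medium at in-plane wavenumber kx
transverse_wavenumber <- function(material, omega, kx, half_space = FALSE) {
  k <- propagation_factor(material, omega)
  ky2 <- k^2 - kx^2
  if (half_space) csqrt_decaying(ky2) else sqrt(ky2)
}

# transverse-line characteristic impedance Zc * ky / k == mu_eff * ky / omega
transverse_impedance <- function(material, omega, ky) {
  effective_modulus(material, omega) * ky / omega
}

#' Surface impedances looking up and down from a reference plane
#'
#' The transverse-resonance formulation evaluates, at a horizontal reference
#' plane, the acoustic impedance looking up (through the finite layers above
#' the plane into the top half-space) and looking down (through the layers
#' below the plane into the substrate half-space). Half-spaces contribute
#' their transverse-line impedance on the decaying branch — a semi-infinite
#' Newtonian liquid directly on the plane presents `sqrt(j omega rho eta)`,
#' the classic liquid-loading impedance. Finite layers are folded in with
#' [transform_impedance()]. A guided mode makes the two impedances sum to
#' zero.
#'
#' @param stack An [layer_stack()].
#' @param omega Angular frequency in rad/s.
#' @param kx Complex in-plane wavenumber (1/m).
#' @param plane Reference-plane index: `0` is the substrate/first-layer
#'   interface, `i` the interface above layer `i`.
#' @return Complex impedance (Pa.s/m).
#' @export
surface_impedance_up <- function(stack, omega, kx, plane = 0) {
  n <- length(stack$layers)
  if (plane < 0 || plane > n) abort("plane out of range")
  top <- stack$top
  if (top$kind == "vacuum") {
    z <- as.complex(0)
  } else {
    ky <- transverse_wavenumber(top, omega, kx, half_space = TRUE)
    z <- transverse_impedance(top, omega, ky)
  }
  if (plane < n) {
    for (i in seq(n, plane + 1)) {
      l <- stack$layers[[i]]
      ky <- transverse_wavenumber(l$material, omega, kx)
      zc <- transverse_impedance(l$material, omega, ky)
      z <- transform_impedance(zc, z, 1i * ky, l$h)
    }
  }
  z
}

#' @rdname surface_impedance_up
#' @export
surface_impedance_down <- function(stack, omega, kx, plane = 0) {
  n <- length(stack$layers)
  if (plane < 0 || plane > n) abort("plane out of range")
  ky <- transverse_wavenumber(stack$substrate, omega, kx, half_space = TRUE)
  z <- transverse_impedance(stack$substrate, omega, ky)
  if (plane > 0) {
    for (i in seq_len(plane)) {
      l <- stack$layers[[i]]
      ky <- transverse_wavenumber(l$material, omega, kx)
      zc <- transverse_impedance(l$material, omega, ky)
      z <- transform_impedance(zc, z, 1i * ky, l$h)
    }
  }
  z
}

# transverse-resonance function and its relative residual
resonance_fn <- function(stack, omega, kx, plane = 0) {
  surface_impedance_up(stack, omega, kx, plane) +
    surface_impedance_down(stack, omega, kx, plane)
}

resonance_residual <- function(stack, omega, kx, plane = 0) {
  zu <- surface_impedance_up(stack, omega, kx, plane)
  zd <- surface_impedance_down(stack, omega, kx, plane)
  # normalize by the stack's own impedance scale so the residual stays
  # meaningful when one side vanishes (e.g. vacuum directly on the plane)
  abs(zu + zd) / max(abs(zu), abs(zd), 0.01 * impedance_scale(stack, omega))
}

impedance_scale <- function(stack, omega) {
  zs <- abs(characteristic_impedance(stack$substrate, omega))
  for (l in stack$layers)
    zs <- max(zs, abs(characteristic_impedance(l$material, omega)))
  zs
}
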