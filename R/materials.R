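#' Acoustic material descriptions
#'
#' A material is a small record of the properties that determine how a plane
#' shear-horizontal wave propagates through it: density `rho` (kg/m3), shear
#' modulus `mu` (Pa) and dynamic viscosity `eta` (Pa.s). The `kind` decides
#' which properties are required and which constitutive law supplies the
#' characteristic acoustic impedance and propagation factor:
#'
#' * `rigid_solid` — lossless elastic solid (`rho`, `mu`);
#' * `viscoelastic_solid` — Kelvin–Voigt-like solid described by a parallel
#'   elementary circuit (`rho`, `mu`, `eta`);
#' * `newtonian_liquid` — purely viscous liquid (`rho`, `eta`);
#' * `vacuum` — zero-impedance termination used as the "air on top" baseline
#'   (shear waves do not propagate into air to any measurable degree).
#'
#' @param name Label used in printing and tables.
#' @param kind One of `"rigid_solid"`, `"viscoelastic_solid"`,
#'   `"newtonian_liquid"`, `"vacuum"`.
#' @param density Mass density in kg/m3 (positive; 0 only for vacuum).
#' @param shear_modulus Shear modulus in Pa (rigid/viscoelastic).
#' @param viscosity Dynamic viscosity in Pa.s (viscoelastic/newtonian).
#' @return An object of class `lw_material`.
#' @seealso [characteristic_impedance()], [propagation_factor()],
#'   [material_library()]
#' @examples
#' su8 <- viscoelastic_solid("SU-8", density = 1100,
#'                           shear_modulus = 1.21e9, viscosity = 0.12)
#' water <- newtonian_liquid("water", density = 997, viscosity = 0.89e-3)
#' @export
material <- function(name, kind, density = NULL, shear_modulus = NULL,
                     viscosity = NULL) {
  kind <- arg_match0(kind, c("rigid_solid", "viscoelastic_solid",
                             "newtonian_liquid", "vacuum"))
  if (kind == "vacuum") {
    density <- density %||% 0
    if (density != 0) abort("vacuum must have zero density")
    m <- list(name = name, kind = kind, rho = 0, mu = NULL, eta = NULL)
    return(structure(m, class = "lw_material"))
  }
  if (is.null(density) || !is.finite(density) || density <= 0)
    abort(sprintf("material '%s': density must be positive", name))
  needs_mu <- kind %in% c("rigid_solid", "viscoelastic_solid")
  needs_eta <- kind %in% c("viscoelastic_solid", "newtonian_liquid")
  if (needs_mu && (is.null(shear_modulus) || shear_modulus <= 0))
    abort(sprintf("material '%s' (%s): shear_modulus must be positive", name, kind))
  if (needs_eta && (is.null(viscosity) || viscosity < 0))
    abort(sprintf("material '%s' (%s): viscosity must be non-negative", name, kind))
  m <- list(name = name, kind = kind, rho = density,
            mu = if (needs_mu) shear_modulus else NULL,
            eta = if (needs_eta) viscosity else NULL)
  structure(m, class = "lw_material")
}

#' @rdname material
#' @export
rigid_solid <- function(name, density, shear_modulus) {
  material(name, "rigid_solid", density, shear_modulus = shear_modulus)
}

#' @rdname material
#' @export
viscoelastic_solid <- function(name, density, shear_modulus, viscosity) {
  material(name, "viscoelastic_solid", density, shear_modulus = shear_modulus,
           viscosity = viscosity)
}

#' @rdname material
#' @export
newtonian_liquid <- function(name, density, viscosity) {
  material(name, "newtonian_liquid", density, viscosity = viscosity)
}

#' @rdname material
#' @export
vacuum_medium <- function(name = "vacuum") material(name, "vacuum")

#' @export
print.lw_material <- function(x, ...) {
  cat(sprintf("<lw_material> %s [%s]\n", x$name, x$kind))
  if (x$kind != "vacuum") cat(sprintf("  rho = %g kg/m3", x$rho))
  if (!is.null(x$mu)) cat(sprintf("  mu = %g Pa", x$mu))
  if (!is.null(x$eta)) cat(sprintf("  eta = %g Pa.s", x$eta))
  cat("\n")
  invisible(x)
}

is_material <- function(x) inherits(x, "lw_material")

# Complex effective shear modulus of a medium under the e^{+j omega t}
# convention: mu for rigid solids, j*omega*eta for Newtonian liquids, and
# j*omega*L/(G + j*omega*C) for the parallel-circuit viscoelastic solid.
effective_modulus <- function(material, omega) {
  switch(material$kind,
    rigid_solid = as.complex(material$mu),
    newtonian_liquid = 1i * omega * material$eta,
    viscoelastic_solid = {
      # Zc^2 = j*omega*L / (G + j*omega*C) = rho * mu_eff with L = rho;
      # algebraically mu_eff = j*omega / (G + j*omega*C) = mu + j*omega*eta
      material$mu + 1i * omega * material$eta
    },
    vacuum = as.complex(0)
  )
}

#' Characteristic acoustic impedance of a medium
#'
#' Ratio of shear stress to particle velocity for a plane shear wave, the
#' transmission-line analogue of a line's characteristic impedance:
#' `sqrt(rho * mu)` for a rigid solid, `sqrt(j * omega * rho * eta)` for a
#' Newtonian liquid, and `sqrt(j * omega * L / (G + j * omega * C))` for the
#' parallel-circuit viscoelastic solid. The complex square root is taken on
#' the branch with non-negative real part (a passive medium absorbs power).
#' A vacuum presents exactly zero impedance.
#'
#' @param material An [material()] object.
#' @param omega Angular frequency in rad/s (positive).
#' @return Complex impedance in Pa.s/m.
#' @examples
#' linbo3 <- rigid_solid("LiNbO3", 4650, 86.3e9)
#' characteristic_impedance(linbo3, 2 * pi * 30e6) # ~2.003e7, purely real
#' @export
characteristic_impedance <- function(material, omega) {
  stopifnot(is_material(material))
  if (any(omega <= 0)) abort("omega must be positive")
  if (material$kind == "vacuum") return(rep(as.complex(0), length(omega)))
  mu_eff <- effective_modulus(material, omega)
  csqrt_passive(material$rho * mu_eff)
}

#' Propagation factor (complex wavenumber) of a medium
#'
#' Complex wavenumber `k` (1/m) of a plane shear wave, under the
#' `e^{+j omega t}` time convention with propagation `e^{-j k x}`:
#' `omega * sqrt(rho / mu_eff)` with the complex effective modulus of the
#' medium's constitutive law. The branch is chosen with `Im(k) <= 0` so the
#' wave decays along its propagation direction in a lossy passive medium;
#' for a lossless rigid solid `k` is purely real. A semi-infinite Newtonian
#' half-space then presents the surface impedance `sqrt(j omega rho eta)`
#' (the classic liquid-loading result for thickness-shear resonators).
#'
#' @inheritParams characteristic_impedance
#' @return Complex wavenumber in 1/m.
#' @examples
#' su8 <- rigid_solid("SU-8 elastic", 1100, 1.21e9)
#' propagation_factor(su8, 2 * pi * 30e6) # ~1.797e5, real
#' @export
propagation_factor <- function(material, omega) {
  stopifnot(is_material(material))
  if (any(omega <= 0)) abort("omega must be positive")
  if (material$kind == "vacuum") return(rep(as.complex(0), length(omega)))
  if (material$kind == "newtonian_liquid" && material$eta == 0)
    abort("propagation factor undefined for an inviscid (eta = 0) liquid")
  mu_eff <- effective_modulus(material, omega)
  csqrt_decaying(omega^2 * material$rho / mu_eff)
}

#' Parallel elementary circuit of a viscoelastic solid
#'
#' Maps shear modulus, viscosity and density onto the parallel-circuit
#' parameters used by the transmission-line analogy for a viscoelastic
#' solid: `C = mu / (omega^2 eta^2 + mu^2)` (1/Pa),
#' `G = eta omega^2 / (omega^2 eta^2 + mu^2)` (1/(Pa.s)) and `L = rho`
#' (kg/m3). In the eta = 0 limit `G = 0` and `C = 1/mu` (pure elasticity);
#' the loss tangent identity `G / (omega C) = omega eta / mu` holds for all
#' parameter values.
#'
#' @param mu Shear modulus in Pa (>= 0).
#' @param eta Viscosity in Pa.s (>= 0); `mu` and `eta` must not both vanish.
#' @param rho Density in kg/m3.
#' @param omega Angular frequency in rad/s.
#' @return A one-row tibble with columns `C`, `G`, `L`, `omega`.
#' @examples
#' viscoelastic_circuit(1.21e9, 0.12, 1100, 2 * pi * 30e6)
#' @export
viscoelastic_circuit <- function(mu, eta, rho, omega) {
  if (mu < 0 || eta < 0) abort("mu and eta must be non-negative")
  if (mu == 0 && eta == 0) abort("mu and eta must not both be zero")
  if (any(omega <= 0)) abort("omega must be positive")
  denom <- omega^2 * eta^2 + mu^2
  tibble(C = mu / denom, G = eta * omega^2 / denom, L = rho, omega = omega)
}
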