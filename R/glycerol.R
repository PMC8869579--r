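# Glycerol-water calibration liquids.
#
# Viscosity: Cheng, Ind. Eng. Chem. Res. 47 (2008) 3285-3288 — exponent
# blending mu = mu_w^alpha * mu_g^(1-alpha) with a temperature-dependent
# weighting alpha(w, T). Density: Volk & Kaehler, Exp. Fluids 59 (2018) 75 —
# linear glycerol/water mixing with a sine-bump volume-contraction
# correction. Both correlations are valid over 0-100 degC and the full
# composition range, which covers calibration liquids up to a few cP amply.

cheng_water_viscosity_cp <- function(temp_c) {
  1.790 * exp((-1230 - temp_c) * temp_c / (36100 + 360 * temp_c))
}

cheng_glycerol_viscosity_cp <- function(temp_c) {
  12100 * exp((-1233 + temp_c) * temp_c / (9900 + 70 * temp_c))
}

cheng_viscosity_cp <- function(w, temp_c) {
  a <- 0.705 - 0.0017 * temp_c
  b <- (4.9 + 0.036 * temp_c) * a^2.5
  alpha <- 1 - w + a * b * w * (1 - w) / (a * w + b * (1 - w))
  mu_w <- cheng_water_viscosity_cp(temp_c)
  mu_g <- cheng_glycerol_viscosity_cp(temp_c)
  mu_w^alpha * mu_g^(1 - alpha)
}

vk_water_density <- function(temp_c) {
  1000 * (1 - abs((temp_c - 3.98) / 615)^1.71)
}

vk_glycerol_density <- function(temp_c) {
  1273.3 - 0.6121 * temp_c
}

vk_density <- function(w, temp_c) {
  a_con <- 1.78e-6 * temp_c^2 - 1.82e-4 * temp_c + 1.41e-2
  kappa <- 1 + a_con * sin(w^1.31 * pi)^0.81
  rho_w <- vk_water_density(temp_c)
  rho_g <- vk_glycerol_density(temp_c)
  rho_w + (rho_g - rho_w) * w * kappa
}

#' Properties of glycerol-water mixtures
#'
#' Dynamic viscosity and density of an aqueous glycerol solution at a given
#' glycerol mass fraction and temperature, from the Cheng (2008) viscosity
#' correlation and the Volk–Kähler (2018) density correlation. These are the
#' standard tools for designing calibration-liquid series of prescribed
#' viscosity (roughly 0.9–4 cP at 25 degC for mass fractions up to ~0.45).
#'
#' @param mass_fraction Glycerol mass fraction w/w, in `[0, 1]`. Vectorised.
#' @param temperature_c Temperature in degrees Celsius, in `[0, 100]`.
#' @return A tibble with columns `mass_fraction`, `temperature_c`,
#'   `viscosity_cp`, `viscosity_pas`, `density_kgm3`.
#' @examples
#' glycerol_properties(c(0, 0.252, 0.4544), 25)
#' @seealso [solve_mass_fraction()] for the inverse problem.
#' @export
glycerol_properties <- function(mass_fraction, temperature_c = 25) {
  if (any(mass_fraction < 0 | mass_fraction > 1))
    abort("mass_fraction must be in [0, 1]")
  if (any(temperature_c < 0 | temperature_c > 100))
    abort("temperature_c must be in [0, 100] degC")
  visc_cp <- cheng_viscosity_cp(mass_fraction, temperature_c)
  tibble(
    mass_fraction = mass_fraction,
    temperature_c = temperature_c,
    viscosity_cp = visc_cp,
    viscosity_pas = cp_to_pas(visc_cp),
    density_kgm3 = vk_density(mass_fraction, temperature_c)
  )
}

#' Glycerol mass fraction achieving a target viscosity
#'
#' Inverts [glycerol_properties()] by monotone bisection: viscosity is
#' strictly increasing in mass fraction at fixed temperature, so the mass
#' fraction delivering a target viscosity is unique when it exists.
#'
#' @param viscosity_cp Target dynamic viscosity in centipoise.
#' @param temperature_c Temperature in degrees Celsius.
#' @param tol Relative tolerance on the recovered viscosity.
#' @return Mass fraction in `[0, 1]`.
#' @examples
#' solve_mass_fraction(1.8, 25) # ~0.252
#' @export
solve_mass_fraction <- function(viscosity_cp, temperature_c = 25, tol = 1e-6) {
  stopifnot(length(viscosity_cp) == 1)
  lo <- cheng_viscosity_cp(0, temperature_c)
  hi <- cheng_viscosity_cp(1, temperature_c)
  if (viscosity_cp < lo * (1 - 1e-12) || viscosity_cp > hi * (1 + 1e-12))
    abort(sprintf(
      "target %.4g cP outside the achievable range [%.4g, %.4g] cP at %g degC",
      viscosity_cp, lo, hi, temperature_c))
  if (viscosity_cp <= lo) return(0)
  if (viscosity_cp >= hi) return(1)
  f <- function(w) cheng_viscosity_cp(w, temperature_c) - viscosity_cp
  root <- uniroot(f, c(0, 1), tol = .Machine$double.eps^0.75)$root
  achieved <- cheng_viscosity_cp(root, temperature_c)
  if (abs(achieved - viscosity_cp) > tol * viscosity_cp)
    abort("bisection failed to meet the requested tolerance")
  root
}

#' A glycerol-water solution as a Newtonian liquid material
#'
#' Convenience wrapper building the [newtonian_liquid()] material for a
#' glycerol solution specified either by mass fraction or by target
#' viscosity (in cP).
#'
#' @param mass_fraction Glycerol mass fraction (exclusive with
#'   `viscosity_cp`).
#' @param viscosity_cp Target viscosity in cP, converted to a mass fraction
#'   with [solve_mass_fraction()].
#' @param temperature_c Temperature in degrees Celsius.
#' @return An `lw_material` of kind `newtonian_liquid`.
#' @examples
#' glycerol_solution(viscosity_cp = 4)
#' @export
glycerol_solution <- function(mass_fraction = NULL, viscosity_cp = NULL,
                              temperature_c = 25) {
  if (is.null(mass_fraction) == is.null(viscosity_cp))
    abort("give exactly one of mass_fraction or viscosity_cp")
  if (is.null(mass_fraction))
    mass_fraction <- solve_mass_fraction(viscosity_cp, temperature_c)
  p <- glycerol_properties(mass_fraction, temperature_c)
  newtonian_liquid(
    sprintf("glycerol %.1f%% w/w (%.3g cP, %g degC)",
            100 * mass_fraction, p$viscosity_cp, temperature_c),
    density = p$density_kgm3, viscosity = p$viscosity_pas)
}
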