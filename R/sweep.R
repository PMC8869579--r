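#' Viscosity sweep of the transmission-line model
#'
#' Solves the guided mode for a sequence of Newtonian top-loading liquids
#' and converts the complex wavenumber into the delay-line observables: the
#' propagation-loss contribution to insertion loss (negative dB, from
#' `Im(k_x)` over the delay path) and the accumulated phase at `f` (degrees,
#' from `Re(k_x)`). Liquids with higher viscosity-density product load the
#' guide harder, so the IL magnitude is non-decreasing along increasing
#' `eta * rho`.
#'
#' @param stack_template An [layer_stack()] whose top half-space is replaced
#'   by each liquid in turn (its own top is ignored).
#' @param liquids Data frame with columns `eta_cP` and `rho_kgm3`, or a list
#'   of [material()] objects (vacuum entries give the unloaded baseline).
#' @param f Frequency in Hz.
#' @param delay_path Acoustic path length in metres.
#' @param ... Passed to [solve_dispersion()].
#' @return A tibble of class `lw_sweep` with columns `eta_cP`, `rho_kgm3`,
#'   `v_phase_mps`, `alpha_dB_per_m`, `IL_dB`, `phase_deg`. Solver failures
#'   for individual liquids become `NA` rows with a warning.
#' @examples
#' \donttest{
#' liquids <- glycerol_properties(c(0, 0.252, 0.4544), 25)
#' viscosity_sweep(reference_stack(),
#'                 data.frame(eta_cP = liquids$viscosity_cp,
#'                            rho_kgm3 = liquids$density_kgm3),
#'                 f = 30e6, delay_path = 37 * 144e-6)
#' }
#' @export
viscosity_sweep <- function(stack_template, liquids, f = 30e6,
                            delay_path = 37 * 144e-6, ...) {
  stopifnot(inherits(stack_template, "lw_stack"))
  liq_list <- as_liquid_list(liquids)
  if (length(liq_list) == 0) abort("liquids must be non-empty")
  rows <- map(liq_list, function(m) {
    st <- stack_template
    st$top <- m
    eta_cp <- if (m$kind == "vacuum") 0 else pas_to_cp(m$eta)
    rho <- if (m$kind == "vacuum") 0 else m$rho
    sol <- tryCatch(solve_dispersion(st, f, ...), error = function(e) {
      warn(sprintf("sweep point eta = %.3g cP failed: %s", eta_cp,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(sol)) {
      return(tibble(eta_cP = eta_cp, rho_kgm3 = rho, v_phase_mps = NA_real_,
                    alpha_dB_per_m = NA_real_, IL_dB = NA_real_,
                    phase_deg = NA_real_))
    }
    tibble(
      eta_cP = eta_cp,
      rho_kgm3 = rho,
      v_phase_mps = sol$phase_velocity,
      alpha_dB_per_m = sol$attenuation_db_per_m,
      IL_dB = -sol$attenuation_db_per_m * delay_path,
      phase_deg = -Re(sol$k_x) * delay_path * 180 / pi
    )
  })
  out <- list_rbind(rows)
  attr(out, "f") <- f
  attr(out, "delay_path") <- delay_path
  class(out) <- c("lw_sweep", class(out))
  out
}

as_liquid_list <- function(liquids) {
  if (is.data.frame(liquids)) {
    nm <- names(liquids)
    eta_col <- intersect(c("eta_cP", "eta_cp", "viscosity_cp"), nm)[1]
    rho_col <- intersect(c("rho_kgm3", "density_kgm3", "rho"), nm)[1]
    if (is.na(eta_col) || is.na(rho_col))
      abort("liquids data frame needs viscosity (eta_cP) and density (rho_kgm3) columns")
    return(pmap(list(liquids[[eta_col]], liquids[[rho_col]]), function(e, r) {
      newtonian_liquid(sprintf("%.3g cP", e), density = r,
                       viscosity = cp_to_pas(e))
    }))
  }
  if (is_material(liquids)) return(list(liquids))
  stopifnot(is.list(liquids), all(vapply(liquids, is_material, logical(1))))
  liquids
}

#' Sensitivity of the sweep observables to viscosity
#'
#' Differentiates the insertion loss and phase columns of a
#' [viscosity_sweep()] table with respect to viscosity by central finite
#' differences on the sweep grid (one-sided at the endpoints) — the
#' derivative-of-the-response definition of sensor sensitivity.
#'
#' @param sweep A tibble with columns `eta_cP`, `IL_dB`, `phase_deg`
#'   (at least two rows, distinct viscosities).
#' @return A tibble with `eta_cP`, `dIL_dB_per_cP`, `dphase_deg_per_cP`.
#' @export
sensitivity <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  sweep <- sweep[order(sweep$eta_cP), ]
  n <- nrow(sweep)
  if (n < 2) abort("sensitivity needs at least two sweep points")
  d <- function(y) {
    x <- sweep$eta_cP
    g <- numeric(n)
    g[1] <- (y[2] - y[1]) / (x[2] - x[1])
    g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
    }
    g
  }
  tibble(eta_cP = sweep$eta_cP,
         dIL_dB_per_cP = d(sweep$IL_dB),
         dphase_deg_per_cP = d(sweep$phase_deg))
}
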