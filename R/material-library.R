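#' Packaged material library
#'
#' The device materials and calibration liquids of the reference 30 MHz
#' sensor ship as a JSON table: the LiNbO3 36Y-X substrate, the Cr/Au
#' metallization, the SU-8 guiding layer (viscoelastic, plus a lossless
#' `SU8_elastic` variant), water and the glycerol calibration liquids at
#' 25 degC, and a vacuum termination.
#'
#' @param name Entry name, e.g. `"LiNbO3_36YX_isotropic"`, `"SU8"`,
#'   `"water_25C"`, `"glycerol_1.8cP"`.
#' @return `material_library()` returns a named list of [material()] objects;
#'   `load_material()` returns a single one.
#' @examples
#' names(material_library())
#' load_material("SU8")
#' @export
material_library <- function() {
  path <- system.file("extdata", "materials.json", package = "lovewave",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  lapply(setNames(names(raw), names(raw)), function(nm) {
    e <- raw[[nm]]
    material(nm, e$kind,
             density = e$density %||% NULL,
             shear_modulus = e$shear_modulus %||% NULL,
             viscosity = e$viscosity %||% NULL)
  })
}

#' @rdname material_library
#' @export
load_material <- function(name) {
  lib <- material_library()
  if (!name %in% names(lib))
    abort(sprintf("unknown material '%s'; available: %s",
                  name, paste(names(lib), collapse = ", ")))
  lib[[name]]
}
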