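#' Layer stacks for the layered shear waveguide
#'
#' A stack is the geometry of the transmission-line model: a substrate
#' half-space, an ordered list of finite layers from the substrate upward,
#' and a top half-space (vacuum for the air baseline, or a liquid). A guided
#' Love solution exists when the slowest shear velocity among the finite
#' layers is below the substrate shear velocity, so energy can be trapped in
#' the overlayer.
#'
#' @param material An [material()] object.
#' @param thickness Layer thickness in metres (positive).
#' @param substrate Substrate half-space material (must carry a shear
#'   modulus).
#' @param layers List of [layer()] objects, ordered from the substrate up.
#' @param top Top half-space material (default vacuum).
#' @return `layer()` returns an `lw_layer`; `layer_stack()` an `lw_stack`.
#' @examples
#' stack <- layer_stack(
#'   substrate = load_material("LiNbO3_36YX_isotropic"),
#'   layers = list(layer(load_material("SU8"), 8e-6)),
#'   top = load_material("water_25C")
#' )
#' @export
layer <- function(material, thickness) {
  stopifnot(is_material(material))
  if (!is.finite(thickness) || thickness < 0)
    abort("layer thickness must be a non-negative length in metres")
  if (material$kind == "vacuum") abort("a finite layer cannot be vacuum")
  structure(list(material = material, h = thickness), class = "lw_layer")
}

#' @rdname layer
#' @export
layer_stack <- function(substrate, layers = list(), top = vacuum_medium()) {
  stopifnot(is_material(substrate), is_material(top))
  if (is.null(substrate$mu))
    abort("the substrate half-space must be a solid (shear modulus required)")
  if (inherits(layers, "lw_layer")) layers <- list(layers)
  ok <- vapply(layers, inherits, logical(1), "lw_layer")
  if (!all(ok)) abort("layers must be a list of layer() objects")
  structure(list(substrate = substrate, layers = layers, top = top),
            class = "lw_stack")
}

#' @export
print.lw_stack <- function(x, ...) {
  cat("<lw_stack>\n")
  cat(sprintf("  top:       %s [%s]\n", x$top$name, x$top$kind))
  for (i in rev(seq_along(x$layers))) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d:   %s [%s], h = %g um\n",
                i, l$material$name, l$material$kind, 1e6 * l$h))
  }
  cat(sprintf("  substrate: %s [%s]\n", x$substrate$name, x$substrate$kind))
  invisible(x)
}

# shear velocity of a solid material (lossless part)
shear_velocity <- function(material) {
  if (is.null(material$mu)) return(NA_real_)
  sqrt(material$mu / material$rho)
}

#' Reference device stack (LiNbO3 / Cr / Au / SU-8)
#'
#' Builds the layer stack of the reference 30 MHz device: a LiNbO3 36Y-X
#' substrate, optional thin Cr (10 nm) and Au (165 nm) metal layers of the
#' grounded sensing path, an SU-8 guiding layer, and a configurable top
#' half-space. The metal layers are modelled as rigid-solid line sections;
#' whether they are included is configurable because their loading is a
#' second-order effect.
#'
#' @param h_guiding SU-8 guiding-layer thickness in metres (default 8 um).
#' @param top Top half-space material (default vacuum).
#' @param include_metal Include the Cr/Au layers (default TRUE).
#' @param guiding SU-8 material to use, by default the viscoelastic entry of
#'   the library; pass `load_material("SU8_elastic")` for a lossless guide.
#' @return An `lw_stack`.
#' @examples
#' reference_stack(top = load_material("water_25C"))
#' @export
reference_stack <- function(h_guiding = 8e-6, top = vacuum_medium(),
                            include_metal = TRUE,
                            guiding = load_material("SU8")) {
  lib <- material_library()
  layers <- list()
  if (include_metal) {
    layers <- list(layer(lib$Cr, 10e-9), layer(lib$Au, 165e-9))
  }
  layers <- c(layers, list(layer(guiding, h_guiding)))
  layer_stack(substrate = lib$LiNbO3_36YX_isotropic, layers = layers, top = top)
}

# Lossless twin of a stack: viscoelastic solids lose their viscosity,
# a Newtonian top half-space is replaced by vacuum (used to bracket the
# real dispersion root before losses are switched on).
lossless_stack <- function(stack) {
  strip <- function(m) {
    switch(m$kind,
      viscoelastic_solid = rigid_solid(m$name, m$rho, m$mu),
      newtonian_liquid = vacuum_medium(m$name),
      m)
  }
  layers <- lapply(stack$layers, function(l) layer(strip(l$material), l$h))
  layer_stack(strip(stack$substrate), layers, strip(stack$top))
}
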