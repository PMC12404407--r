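#' Material specification for a phantom region
#'
#' Bundles the mechanical and optical properties attached to one region of a
#' digital phantom: a Young's modulus (kPa, quoted at a reference strain), an
#' OCT backscatter level in dB relative to the system noise floor, and flags
#' for fluid (load-bearing but very soft, optically scattering) and void
#' (hollow: no material, no signal) regions.
#'
#' @param name Character label for the material.
#' @param youngs_modulus_kpa Young's modulus E in kPa. Must be positive unless
#'   the material is a void.
#' @param backscatter_db Mean OCT backscatter in dB above the noise floor.
#' @param is_fluid Logical; fluid regions carry a small effective modulus and
#'   matched backscatter.
#' @param is_void Logical; void regions have no material (no stiffness, no
#'   signal) and are excluded from mechanics and masked in reconstructions.
#' @return An object of class `material_spec`.
#' @export
#' @examples
#' material_spec("stroma", 48, 30)
material_spec <- function(name, youngs_modulus_kpa, backscatter_db = 0,
                          is_fluid = FALSE, is_void = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is_void && is_fluid)
    stop("a material cannot be both void and fluid")
  if (!is_void) {
    if (!is.finite(youngs_modulus_kpa) || youngs_modulus_kpa <= 0)
      stop("youngs_modulus_kpa must be positive for non-void materials")
  }
  if (!is.finite(backscatter_db))
    stop("backscatter_db must be finite")
  structure(
    list(name = name,
         youngs_modulus_kpa = if (is_void) NA_real_ else youngs_modulus_kpa,
         backscatter_db = backscatter_db,
         is_fluid = isTRUE(is_fluid),
         is_void = isTRUE(is_void)),
    class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  kind <- if (x$is_void) "void" else if (x$is_fluid) "fluid" else "solid"
  cat(sprintf("<material_spec> %s (%s): E = %s kPa, backscatter = %g dB\n",
              x$name, kind,
              if (is.na(x$youngs_modulus_kpa)) "-" else
                format(x$youngs_modulus_kpa),
              x$backscatter_db))
  invisible(x)
}

#' Default material table for the three-region IDC-mimicking phantom
#'
#' Elasticities are the fabrication reference values at 10% strain
#' (adipose 18 kPa, stroma 48 kPa, IDC 230 kPa); backscatter levels follow the
#' measured en-face OCT contrast of the fabricated phantom, where stroma is the
#' brightest region (about 30 dB), IDC intermediate (23 dB) and adipose
#' darkest (17 dB).
#'
#' @return Named list of `material_spec` (names: adipose, stroma, idc).
#' @export
idc_phantom_materials <- function() {
  list(adipose = material_spec("adipose", 18, 17),
       stroma  = material_spec("stroma", 48, 30),
       idc     = material_spec("idc", 230, 23))
}

#' Default bulk material for the duct-mimicking phantom
#'
#' The duct phantom bulk silicone measures about 58 kPa at 10% axial strain.
#' Backscatter defaults to 25 dB (TiO2-scattering bulk).
#'
#' @return A `material_spec`.
#' @export
duct_bulk_material <- function() material_spec("bulk", 58, 25)

#' Duct-lumen materials
#'
#' A hollow duct is a void: no load-bearing material and no OCT signal. A
#' fluid-filled duct carries a small positive effective modulus (default
#' 1 kPa) so the one-dimensional mechanics can express that the lumen deforms
#' more than the surrounding cured silicone, and a backscatter level matched
#' to the bulk (the fill fluid is loaded with the same scatterers).
#'
#' @param effective_modulus_kpa Effective modulus of the fill fluid, kPa.
#' @param backscatter_db Backscatter of the fill fluid, dB.
#' @return A `material_spec`.
#' @export
duct_fluid_material <- function(effective_modulus_kpa = 1,
                                backscatter_db = 25) {
  material_spec("duct_fluid", effective_modulus_kpa, backscatter_db,
                is_fluid = TRUE)
}

#' @rdname duct_fluid_material
#' @export
duct_void_material <- function() {
  # backscatter is nominal: void voxels are simulated as noise-only anyway
  material_spec("duct_void", NA_real_, -60, is_void = TRUE)
}
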