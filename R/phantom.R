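# Digital phantoms: a 3D integer label grid plus per-region materials.
#
# Axis convention used throughout the package: arrays are indexed [x, y, z]
# with 1-based voxel indices; z points from the imaging window (z index 1)
# downward into the sample, so the fixed compression plate sits at the last
# z plane. Voxel k spans the half-open interval [(k-1)*dz, k*dz).

#' Construct a phantom model
#'
#' @param labels 3D integer array of region ids (values must appear in
#'   `names(materials)` after coercion to character, or be integer ids
#'   matching `materials` names).
#' @param materials Named list of [material_spec()]; names are the character
#'   form of the label integers.
#' @param pitch_um Numeric length-3, voxel pitch (dx, dy, dz) in micrometres.
#' @param layer Optional `compliant_layer` already attached (see
#'   [attach_layer()]); usually `NULL` at construction.
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(labels, materials, pitch_um, layer = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(dim(labels) < 1L)) stop("label grid must be non-empty")
  if (length(pitch_um) != 3L || any(!is.finite(pitch_um)) ||
      any(pitch_um <= 0))
    stop("pitch_um must be three positive numbers (dx, dy, dz)")
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(present), names(materials))
  if (length(missing) > 0L)
    stop("labels without a material_spec: ", paste(missing, collapse = ", "))
  for (m in materials)
    if (!inherits(m, "material_spec"))
      stop("all materials must be material_spec objects")
  structure(
    list(labels = labels, materials = materials,
         pitch_um = as.numeric(pitch_um), layer = layer,
         interface_z = 0L),
    class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom_model> %d x %d x %d voxels at (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$pitch_um[1], x$pitch_um[2], x$pitch_um[3]))
  tab <- table(x$labels)
  for (id in names(tab)) {
    m <- x$materials[[id]]
    cat(sprintf("  region %s (%s): %s voxels\n", id, m$name,
                format(as.integer(tab[[id]]), big.mark = ",")))
  }
  if (!is.null(x$layer))
    cat(sprintf("  compliant layer: %g um, secant %g kPa (interface at z=%d)\n",
                x$layer$thickness_um, x$layer$secant_modulus_kpa,
                x$interface_z))
  invisible(x)
}

#' Per-voxel Young's modulus grid of a phantom
#'
#' @param phantom A `phantom_model`.
#' @return 3D numeric array of E in kPa; `NA` for void voxels.
#' @export
modulus_grid <- function(phantom) {
  lut <- material_lookup(phantom, "youngs_modulus_kpa")
  array(lut[as.vector(phantom$labels) + 1L], dim = dim(phantom$labels))
}

#' Per-voxel backscatter grid of a phantom (dB above noise floor)
#'
#' @param phantom A `phantom_model`.
#' @return 3D numeric array; `NA` for void voxels (simulated as noise-only).
#' @export
backscatter_grid <- function(phantom) {
  lut <- material_lookup(phantom, "backscatter_db")
  void <- material_lookup(phantom, "is_void")
  lut[void > 0] <- NA_real_
  array(lut[as.vector(phantom$labels) + 1L], dim = dim(phantom$labels))
}

# lookup table indexed by label id + 1 (labels assumed small non-negative ints)
material_lookup <- function(phantom, field) {
  ids <- as.integer(names(phantom$materials))
  if (any(is.na(ids)) || any(ids < 0))
    stop("material ids must be small non-negative integers")
  lut <- rep(NA_real_, max(ids) + 1L)
  for (i in seq_along(ids))
    lut[ids[i] + 1L] <- as.numeric(phantom$materials[[i]][[field]])
  lut
}

#' Region label constants of the three-region IDC phantom
#' @export
IDC_LABELS <- c(adipose = 0L, stroma = 1L, idc = 2L)

#' Build the three-region IDC-mimicking phantom from two binary masks
#'
#' Mirrors the mold-based assembly: the dense-tissue mask (stroma + IDC) is
#' extruded along z into a structured section, the IDC mask carves the IDC
#' material out of it, and everything outside the dense mask is
#' adipose-mimicking material. Above the structured section sits a thin cover
#' layer (the offset silicone poured over the assembled casting) and below it
#' a base section, giving the assembled slab thickness.
#'
#' @param dense_mask Logical/0-1 matrix: dense tissue (stroma plus IDC).
#' @param idc_mask Logical/0-1 matrix, same shape, subset of `dense_mask`.
#' @param heights_um Named numeric: thicknesses of the `cover`, `structure`
#'   and `base` sections in micrometres (defaults 200 / 1000 / 1000, i.e. a
#'   2.2 mm slab).
#' @param pitch_um Voxel pitch (dx, dy, dz) in micrometres.
#' @param materials Named list with `adipose`, `stroma`, `idc` material specs;
#'   defaults to [idc_phantom_materials()].
#' @param cover_material Which material fills the cover section: `"stroma"`
#'   (default) or `"adipose"`. The base section is adipose (the first-cast
#'   surround).
#' @return A `phantom_model` with labels 0 = adipose, 1 = stroma, 2 = IDC.
#' @export
make_idc_phantom <- function(dense_mask, idc_mask = NULL,
                             heights_um = c(cover = 200, structure = 1000,
                                            base = 1000),
                             pitch_um = c(15, 15, 3.5),
                             materials = idc_phantom_materials(),
                             cover_material = c("stroma", "adipose")) {
  cover_material <- match.arg(cover_material)
  dense_mask <- as_mask(dense_mask)
  if (is.null(idc_mask)) idc_mask <- matrix(FALSE, nrow(dense_mask),
                                            ncol(dense_mask))
  idc_mask <- as_mask(idc_mask)
  if (!identical(dim(dense_mask), dim(idc_mask)))
    stop("dense_mask and idc_mask must have the same shape")
  outside <- sum(idc_mask & !dense_mask)
  if (outside > 0L)
    stop(sprintf("idc_mask extends outside dense_mask by %d pixel(s)",
                 outside))
  for (nm in c("cover", "structure", "base"))
    if (is.na(heights_um[nm]) || heights_um[nm] < 0)
      stop("heights_um must contain non-negative cover/structure/base")

  dz <- pitch_um[3]
  n_cover <- as.integer(round(heights_um[["cover"]] / dz))
  n_struct <- as.integer(round(heights_um[["structure"]] / dz))
  n_base <- as.integer(round(heights_um[["base"]] / dz))
  if (n_struct < 1L) stop("structure section must span at least one voxel")

  plane <- matrix(IDC_LABELS[["adipose"]], nrow(dense_mask), ncol(dense_mask))
  plane[dense_mask] <- IDC_LABELS[["stroma"]]
  plane[idc_mask] <- IDC_LABELS[["idc"]]
  cover_lab <- IDC_LABELS[[cover_material]]

  nz <- n_cover + n_struct + n_base
  labels <- array(IDC_LABELS[["adipose"]],
                  dim = c(nrow(dense_mask), ncol(dense_mask), nz))
  if (n_cover > 0L) labels[, , seq_len(n_cover)] <- cover_lab
  labels[, , n_cover + seq_len(n_struct)] <- as.vector(plane)
  # base planes stay adipose

  mats <- list()
  mats[[as.character(IDC_LABELS[["adipose"]])]] <- materials$adipose
  mats[[as.character(IDC_LABELS[["stroma"]])]] <- materials$stroma
  mats[[as.character(IDC_LABELS[["idc"]])]] <- materials$idc
  ph <- phantom_model(labels, mats, pitch_um)
  ph$structure_z <- n_cover + seq_len(n_struct)
  ph
}

#' Build a homogeneous slab phantom
#'
#' Convenience constructor for recovery experiments: one material everywhere.
#'
#' @param shape Integer length-3 grid shape (nx, ny, nz).
#' @param material A `material_spec`.
#' @param pitch_um Voxel pitch in micrometres.
#' @return A `phantom_model` (single label 0).
#' @export
make_slab_phantom <- function(shape, material, pitch_um = c(15, 15, 3.5)) {
  labels <- array(0L, dim = shape)
  phantom_model(labels, stats::setNames(list(material), "0"), pitch_um)
}

#' Compliant-layer specification
#'
#' The calibrated soft silicone layer placed on the sample surface. Its
#' (monotone) stress-strain curve converts the measured layer strain into the
#' axial stress at the sample surface. The default is a linear curve with a
#' 16 kPa secant modulus and 500 um thickness.
#'
#' @param thickness_um Layer thickness in micrometres.
#' @param stress_strain Function mapping strain magnitude (unitless, on
#'   [0, 0.2]) to stress in kPa; must satisfy f(0) = 0 and be strictly
#'   increasing on [0, 0.2].
#' @param secant_modulus_kpa Secant modulus at 10% strain, kPa (used for the
#'   layer's effective stiffness in forward mechanics).
#' @param backscatter_db OCT backscatter of the scattering part of the layer.
#' @return An object of class `compliant_layer`.
#' @export
compliant_layer <- function(thickness_um = 500,
                            stress_strain = NULL,
                            secant_modulus_kpa = 16,
                            backscatter_db = 25) {
  if (thickness_um <= 0) stop("thickness_um must be positive")
  if (is.null(stress_strain)) {
    E <- secant_modulus_kpa
    stress_strain <- function(strain) E * strain
  }
  if (abs(stress_strain(0)) > 1e-12)
    stop("stress_strain(0) must be 0")
  eps <- seq(0, 0.2, length.out = 41)
  sig <- vapply(eps, stress_strain, numeric(1))
  if (any(diff(sig) <= 0))
    stop("stress_strain must be strictly increasing on [0, 0.2]")
  structure(list(thickness_um = thickness_um,
                 stress_strain = stress_strain,
                 secant_modulus_kpa = secant_modulus_kpa,
                 backscatter_db = backscatter_db),
            class = "compliant_layer")
}

#' Attach a compliant layer on top of a phantom
#'
#' Prepends layer voxel planes at the imaging-window side (smallest z); the
#' layer thickness is rounded to the nearest whole number of planes (always
#' within half a voxel). The layer is stored on the phantom and
#' `interface_z` records the last layer plane (the layer-sample interface).
#'
#' @param phantom A `phantom_model` without a layer.
#' @param layer A [compliant_layer()].
#' @return A new `phantom_model` with the layer planes prepended.
#' @export
attach_layer <- function(phantom, layer = compliant_layer()) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(layer, "compliant_layer"))
  if (!is.null(phantom$layer))
    stop("phantom already has a compliant layer attached")
  dz <- phantom$pitch_um[3]
  # thickness is rounded to the nearest voxel multiple (always within dz/2)
  n_layer <- round(layer$thickness_um / dz)
  if (n_layer < 1L) stop("layer thinner than one voxel plane")

  ids <- as.integer(names(phantom$materials))
  layer_id <- max(ids) + 1L
  d <- dim(phantom$labels)
  labels <- array(0L, dim = c(d[1], d[2], d[3] + n_layer))
  labels[, , seq_len(n_layer)] <- layer_id
  labels[, , n_layer + seq_len(d[3])] <- phantom$labels

  mats <- phantom$materials
  mats[[as.character(layer_id)]] <-
    material_spec("layer", layer$secant_modulus_kpa, layer$backscatter_db)
  out <- phantom_model(labels, mats, phantom$pitch_um, layer = layer)
  out$interface_z <- as.integer(n_layer)
  out$layer_id <- layer_id
  if (!is.null(phantom$structure_z))
    out$structure_z <- phantom$structure_z + n_layer
  out
}

# coerce 0/255 or logical rasters to logical matrix
as_mask <- function(x) {
  if (!is.matrix(x)) stop("mask must be a matrix")
  if (is.logical(x)) return(x)
  x > max(x, 0) / 2 & x > 0
}
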