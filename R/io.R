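# Serialization: masks as single-channel PNG (0 = background,
# 255 = foreground), volumes as multi-page 32-bit TIFF with an affine
# value scale recorded in a YAML sidecar, phantoms as a directory of both.

#' Write / read a binary mask as single-channel PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `read_mask_png` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(t(as_mask(mask)) * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  t(img) > 0.5
}

#' Write / read a 3D volume as multi-page TIFF plus YAML sidecar
#'
#' Values are affinely mapped to [0, 1] for 32-bit TIFF storage; the range,
#' pitch and any extra metadata go to `<path>.yml`. NA voxels are stored as
#' the minimum value and re-masked on read via a companion validity TIFF
#' when `valid` is given.
#'
#' @param volume 3D numeric array.
#' @param path TIFF path (one page per z plane).
#' @param pitch_um Voxel pitch recorded in the sidecar.
#' @param valid Optional 3D logical array written to `<path>.valid.tif`.
#' @param extra Named list merged into the sidecar.
#' @return `read_volume_tiff` returns a list with `volume`, `valid`,
#'   `pitch_um` and `meta`.
#' @export
write_volume_tiff <- function(volume, path, pitch_um = c(1, 1, 1),
                              valid = NULL, extra = list()) {
  d <- dim(volume)
  v <- volume
  v[!is.finite(v)] <- NA
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  scaled <- (v - rng[1]) / diff(rng)
  scaled[is.na(scaled)] <- 0
  pages <- lapply(seq_len(d[3]), function(k) t(scaled[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  if (!is.null(valid)) {
    vpages <- lapply(seq_len(d[3]), function(k) t(valid[, , k]) * 1)
    tiff::writeTIFF(vpages, paste0(path, ".valid.tif"),
                    bits.per.sample = 8L)
  }
  side <- c(list(shape = as.integer(d), value_min = rng[1],
                 value_max = rng[2], pitch_um = as.numeric(pitch_um),
                 has_valid = !is.null(valid)), extra)
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(unlist(side$shape))
  vol <- array(NA_real_, dim = d)
  for (k in seq_len(d[3])) vol[, , k] <- t(pages[[k]])
  vol <- vol * (side$value_max - side$value_min) + side$value_min
  valid <- NULL
  if (isTRUE(side$has_valid)) {
    vp <- tiff::readTIFF(paste0(path, ".valid.tif"), all = TRUE)
    valid <- array(FALSE, dim = d)
    for (k in seq_len(d[3])) valid[, , k] <- t(vp[[k]]) > 0.5
    vol[!valid] <- NA_real_
  }
  list(volume = vol, valid = valid,
       pitch_um = as.numeric(unlist(side$pitch_um)), meta = side)
}

#' Write / read a phantom model as a directory
#'
#' The label grid goes to `labels.tif` (8-bit, label/255), materials, pitch
#' and layer parameters to `phantom.yml`.
#'
#' @param phantom A `phantom_model`.
#' @param dir Output directory.
#' @return `read_phantom` returns a `phantom_model` (a linear stress-strain
#'   curve is reconstructed from the stored secant modulus).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(phantom$labels)
  pages <- lapply(seq_len(d[3]), function(k) t(phantom$labels[, , k]) / 255)
  tiff::writeTIFF(pages, file.path(dir, "labels.tif"), bits.per.sample = 8L)
  mats <- lapply(phantom$materials, function(m)
    list(name = m$name, youngs_modulus_kpa = m$youngs_modulus_kpa,
         backscatter_db = m$backscatter_db, is_fluid = m$is_fluid,
         is_void = m$is_void))
  side <- list(shape = as.integer(d), pitch_um = phantom$pitch_um,
               materials = mats, interface_z = phantom$interface_z)
  if (!is.null(phantom$layer))
    side$layer <- list(thickness_um = phantom$layer$thickness_um,
                       secant_modulus_kpa = phantom$layer$secant_modulus_kpa,
                       backscatter_db = phantom$layer$backscatter_db)
  yaml::write_yaml(side, file.path(dir, "phantom.yml"))
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "phantom.yml"))
  pages <- tiff::readTIFF(file.path(dir, "labels.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(unlist(side$shape))
  labels <- array(0L, dim = d)
  for (k in seq_len(d[3]))
    labels[, , k] <- as.integer(round(t(pages[[k]]) * 255))
  mats <- lapply(side$materials, function(m)
    material_spec(m$name,
                  if (is.null(m$youngs_modulus_kpa) ||
                      isTRUE(m$is_void)) NA_real_ else m$youngs_modulus_kpa,
                  m$backscatter_db, isTRUE(m$is_fluid), isTRUE(m$is_void)))
  layer <- NULL
  if (!is.null(side$layer))
    layer <- compliant_layer(side$layer$thickness_um,
                             secant_modulus_kpa =
                               side$layer$secant_modulus_kpa,
                             backscatter_db = side$layer$backscatter_db)
  ph <- phantom_model(labels, mats, as.numeric(unlist(side$pitch_um)),
                      layer = layer)
  ph$interface_z <- as.integer(side$interface_z)
  ph
}

#' Export an en-face dB image as 8-bit PNG with a stated dB window
#'
#' @param enface_db Numeric matrix of dB values.
#' @param path PNG path.
#' @param window_db Length-2 display window; values are clipped.
#' @export
write_enface_png <- function(enface_db, path, window_db = c(0, 40)) {
  img <- (enface_db - window_db[1]) / diff(window_db)
  img[img < 0] <- 0; img[img > 1] <- 1
  img[is.na(img)] <- 0
  png::writePNG(t(img), path)
  invisible(path)
}
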