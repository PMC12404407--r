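# Two-step en-face segmentation: dense tissue (stroma + IDC) is separated
# from adipose by an OCT SNR threshold with hole filling and a
# connected-component area criterion; the IDC delineation is ingested as a
# given mask (from co-registered histology) and combined with the dense mask.

#' Segmentation parameters
#'
#' Defaults follow the wide-field en-face protocol: a 23 dB SNR threshold and
#' a 10,000-pixel (4 mm^2 at ~20 um pitch) connectivity criterion.
#'
#' @param snr_threshold_db SNR threshold in dB (mask = image >= threshold).
#' @param min_area_px Minimum connected-component area in pixels.
#' @param fill_holes Fill enclosed background holes inside components.
#' @param connectivity 4 or 8 (default 8).
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(snr_threshold_db = 23, min_area_px = 10000,
                                fill_holes = TRUE, connectivity = 8) {
  if (min_area_px < 0) stop("min_area_px must be >= 0")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(snr_threshold_db = snr_threshold_db,
                 min_area_px = as.integer(min_area_px),
                 fill_holes = isTRUE(fill_holes),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Convert an area in mm^2 to pixels at a given pitch
#'
#' Convenience converter for the connectivity criterion. Note that the
#' canonical 10,000 px = 4 mm^2 equivalence corresponds to a 20 um pitch,
#' which is a rounding of the 16 mm / 808 A-scan wide-field pitch (19.8 um).
#'
#' @param area_mm2 Area in mm^2.
#' @param pitch_um Lateral pitch (dx, dy) in micrometres.
#' @return Pixel count (rounded).
#' @export
area_mm2_to_px <- function(area_mm2, pitch_um = c(20, 20)) {
  as.integer(round(area_mm2 * 1e6 / (pitch_um[1] * pitch_um[2])))
}

#' Segment dense tissue from an en-face SNR image
#'
#' Thresholds the image at `snr_threshold_db`, optionally fills holes
#' enclosed by the foreground, and removes connected components smaller than
#' `min_area_px`.
#'
#' @param enface_db 2D numeric matrix of SNR values in dB.
#' @param params A [segmentation_params()].
#' @return Logical matrix (the dense-tissue mask).
#' @export
segment_dense_tissue <- function(enface_db, params = segmentation_params()) {
  enface_db <- as.matrix(enface_db)
  mask <- !is.na(enface_db) & enface_db >= params$snr_threshold_db
  if (params$fill_holes)
    mask <- EBImage::fillHull(mask * 1) > 0
  lab <- label_components(mask, params$connectivity)
  if (params$min_area_px > 0 && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= params$min_area_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1)        # 4-connected labeling
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L) {
    # merge labels that touch diagonally via union-find over label pairs
    pairs <- diagonal_pairs(lab)
    if (nrow(pairs) > 0L) {
      parent <- seq_len(max(lab))
      find <- function(i) {
        while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(max(lab)), find, integer(1))
      dense <- match(roots, sort(unique(roots)))
      lab[lab > 0] <- dense[lab[lab > 0]]
    }
  }
  lab
}

# unique pairs of distinct labels that touch along the two diagonals
diagonal_pairs <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  collect <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  p1 <- collect(lab[-nr, -nc], lab[-1, -1])     # down-right diagonal
  p2 <- collect(lab[-nr, -1], lab[-1, -nc])     # down-left diagonal
  unique(rbind(p1, p2))
}

#' Combine the dense and IDC masks into a three-class label image
#'
#' @param dense_mask Logical matrix (stroma + IDC).
#' @param idc_mask Logical matrix; pixels outside `dense_mask` are clipped
#'   with a warning.
#' @return Integer matrix: 0 = adipose, 1 = stroma, 2 = IDC.
#' @export
combine_region_masks <- function(dense_mask, idc_mask) {
  dense_mask <- as_mask(dense_mask); idc_mask <- as_mask(idc_mask)
  if (!identical(dim(dense_mask), dim(idc_mask)))
    stop("masks must have the same shape")
  outside <- idc_mask & !dense_mask
  if (any(outside)) {
    warning(sprintf("clipping %d IDC pixel(s) outside the dense mask",
                    sum(outside)))
    idc_mask <- idc_mask & dense_mask
  }
  lab <- matrix(0L, nrow(dense_mask), ncol(dense_mask))
  lab[dense_mask] <- 1L
  lab[idc_mask] <- 2L
  lab
}

#' Rasterize a polygon (vertices in mm) into a binary mask
#'
#' Even-odd-rule rasterization: a pixel is foreground when its centre has an
#' odd crossing number. Pixel centres are at `(i - 0.5) * pitch` mm.
#' Self-intersecting polygons follow even-odd semantics; degenerate polygons
#' give an empty mask.
#'
#' @param vertices n x 2 matrix of polygon vertices in mm (n >= 3).
#' @param shape Length-2 mask shape (nx, ny).
#' @param pitch_um Lateral pitch (dx, dy) in micrometres.
#' @return Logical matrix.
#' @export
polygon_to_mask <- function(vertices, shape, pitch_um = c(20, 20)) {
  if (!is.matrix(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be an n x 2 matrix with n >= 3")
  px <- (seq_len(shape[1]) - 0.5) * pitch_um[1] / 1000
  py <- (seq_len(shape[2]) - 0.5) * pitch_um[2] / 1000
  X <- matrix(px, shape[1], shape[2])
  Y <- matrix(py, shape[1], shape[2], byrow = TRUE)
  n <- nrow(vertices)
  crossings <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(n)) {
    a <- vertices[i, ]
    b <- vertices[if (i == n) 1L else i + 1L, ]
    if (a[2] == b[2]) next                 # horizontal edge: no crossing
    straddles <- (Y >= pmin(a[2], b[2])) & (Y < pmax(a[2], b[2]))
    x_int <- a[1] + (Y - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
    crossings <- crossings + (straddles & X < x_int)
  }
  crossings %% 2L == 1L
}
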