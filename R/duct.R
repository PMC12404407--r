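# Branching duct networks: centerline polylines with per-segment diameters,
# rasterized into circular-cross-section channels.

#' Duct network specification
#'
#' @param segments List of segments, each a list with `points` (n x 3 matrix
#'   of centerline coordinates in mm, n >= 2) and `diameter_mm` (> 0).
#' @param fill `"hollow"` (void lumen) or `"fluid"` (fluid-filled lumen).
#' @param fluid_material `material_spec` of the fill fluid; required when
#'   `fill = "fluid"` (defaults to [duct_fluid_material()]).
#' @return An object of class `duct_network_spec`.
#' @export
duct_network_spec <- function(segments, fill = c("hollow", "fluid"),
                              fluid_material = NULL) {
  fill <- match.arg(fill)
  for (seg in segments) {
    p <- seg$points
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L)
      stop("each segment needs a points matrix (>= 2 rows, 3 columns, mm)")
    if (!is.numeric(seg$diameter_mm) || seg$diameter_mm <= 0)
      stop("segment diameters must be positive")
  }
  if (fill == "fluid" && is.null(fluid_material))
    fluid_material <- duct_fluid_material()
  if (fill == "fluid" && !inherits(fluid_material, "material_spec"))
    stop("fluid fill requires a material_spec for the fluid")
  structure(list(segments = segments, fill = fill,
                 fluid_material = fluid_material),
            class = "duct_network_spec")
}

#' Default duct network: 1 mm main duct with a 0.8 mm branch at 11 mm
#'
#' A gently curved main duct (diameter 1 mm, arc length 22 mm) with a single
#' branch (diameter 0.8 mm, length 8 mm) leaving the main centerline at
#' 11 mm arc length from its start, all in the mid-plane of the phantom disc.
#' Coordinates are mm, with the network centred near the origin in x-y and
#' at z = 0.
#'
#' @param fill `"hollow"` or `"fluid"`.
#' @param fluid_material Passed to [duct_network_spec()].
#' @return A `duct_network_spec`.
#' @export
default_duct_network <- function(fill = c("hollow", "fluid"),
                                 fluid_material = NULL) {
  fill <- match.arg(fill)
  # main duct: circular arc of radius 40 mm, arc length 22 mm
  R <- 40
  s <- seq(0, 22, by = 0.25)
  theta <- s / R
  main <- cbind(x = R * sin(theta) - 11,        # roughly centred
                y = R * (1 - cos(theta)) - 1.5,
                z = 0)
  # branch point at arc length 11 mm, tangent there, branch at ~40 degrees
  sb <- 11
  thb <- sb / R
  p0 <- c(R * sin(thb) - 11, R * (1 - cos(thb)) - 1.5, 0)
  tangent <- c(cos(thb), sin(thb), 0)
  ang <- 40 * pi / 180
  dirb <- c(cos(ang) * tangent[1] - sin(ang) * tangent[2],
            sin(ang) * tangent[1] + cos(ang) * tangent[2], 0)
  sb_seq <- seq(0, 8, by = 0.25)
  # slight curvature on the branch as well
  curve <- 0.012 * sb_seq^2
  normal <- c(-dirb[2], dirb[1], 0)
  branch <- cbind(p0[1] + dirb[1] * sb_seq + normal[1] * curve,
                  p0[2] + dirb[2] * sb_seq + normal[2] * curve,
                  0)
  colnames(branch) <- c("x", "y", "z")
  duct_network_spec(
    segments = list(list(points = main, diameter_mm = 1.0, name = "main"),
                    list(points = branch, diameter_mm = 0.8,
                         name = "branch")),
    fill = fill, fluid_material = fluid_material)
}

#' Minimum distance from every voxel centre to a centerline polyline
#'
#' @param polyline n x 3 matrix of points in mm.
#' @param shape Integer length-3 grid shape (nx, ny, nz).
#' @param pitch_um Voxel pitch in micrometres.
#' @param origin_mm Coordinate of the centre of voxel (1,1,1), mm.
#' @return 3D numeric array of distances in mm.
#' @export
rasterize_centerline_distance <- function(polyline, shape, pitch_um,
                                          origin_mm = c(0, 0, 0)) {
  if (!is.matrix(polyline) || ncol(polyline) != 3L || nrow(polyline) < 2L)
    stop("polyline must be an n x 3 matrix with n >= 2")
  pitch_mm <- pitch_um / 1000
  xs <- origin_mm[1] + (seq_len(shape[1]) - 1) * pitch_mm[1]
  ys <- origin_mm[2] + (seq_len(shape[2]) - 1) * pitch_mm[2]
  zs <- origin_mm[3] + (seq_len(shape[3]) - 1) * pitch_mm[3]
  d2 <- array(Inf, dim = shape)
  for (i in seq_len(nrow(polyline) - 1L)) {
    d2 <- pmin(d2, segment_dist2_grid(polyline[i, ], polyline[i + 1L, ],
                                      xs, ys, zs))
  }
  sqrt(d2)
}

# squared distance from every grid point to one segment a-b, fully vectorized
segment_dist2_grid <- function(a, b, xs, ys, zs) {
  ab <- b - a
  len2 <- sum(ab^2)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (len2 == 0) {
    dx2 <- (xs - a[1])^2; dy2 <- (ys - a[2])^2; dz2 <- (zs - a[3])^2
    return(outer(outer(dx2, dy2, `+`), dz2, `+`))
  }
  # projection parameter t = ((p - a).ab)/|ab|^2 separates by axis
  tx <- (xs - a[1]) * ab[1] / len2
  ty <- (ys - a[2]) * ab[2] / len2
  tz <- (zs - a[3]) * ab[3] / len2
  t <- outer(outer(tx, ty, `+`), tz, `+`)
  t[t < 0] <- 0; t[t > 1] <- 1
  cx <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz)) - (a[1] + t * ab[1])
  cy <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz)) -
    (a[2] + t * ab[2])
  cz <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz)) - (a[3] + t * ab[3])
  cx * cx + cy * cy + cz * cz
}

# flat-capped tube membership: perpendicular distance <= r with the axial
# projection inside [0, 1]; polyline sampling is fine enough that wedge gaps
# at gentle bends are below voxel scale, and flat end caps keep the swept
# volume at the analytic cylinder value
segment_tube_inside_grid <- function(a, b, xs, ys, zs, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  grid3 <- function(v, axis) {
    if (axis == 1) array(rep(v, times = ny * nz), dim = c(nx, ny, nz))
    else if (axis == 2) array(rep(rep(v, each = nx), times = nz),
                              dim = c(nx, ny, nz))
    else array(rep(v, each = nx * ny), dim = c(nx, ny, nz))
  }
  if (len2 == 0) return(array(FALSE, dim = c(nx, ny, nz)))
  tx <- (xs - a[1]) * ab[1] / len2
  ty <- (ys - a[2]) * ab[2] / len2
  tz <- (zs - a[3]) * ab[3] / len2
  t <- outer(outer(tx, ty, `+`), tz, `+`)
  inside_t <- t >= 0 & t <= 1
  cx <- grid3(xs, 1) - (a[1] + t * ab[1])
  cy <- grid3(ys, 2) - (a[2] + t * ab[2])
  cz <- grid3(zs, 3) - (a[3] + t * ab[3])
  inside_t & (cx * cx + cy * cy + cz * cz) <= r * r
}

#' Duct region label constants
#' @export
DUCT_LABELS <- c(bulk = 0L, duct = 1L)

#' Rasterize a duct network into a labeled phantom
#'
#' Voxels whose centre lies within `diameter/2` of any segment centerline are
#' labeled as duct lumen (void for hollow fill, fluid material otherwise);
#' branch junctions are the voxel-wise union of the swept circles. By default
#' the grid is sized to enclose the network with a stated margin.
#'
#' @param spec A [duct_network_spec()].
#' @param shape Optional grid shape; computed from the network extent plus
#'   `margin_mm` when `NULL`.
#' @param pitch_um Voxel pitch in micrometres.
#' @param bulk_material Material of the surrounding silicone
#'   (default [duct_bulk_material()]).
#' @param margin_mm Margin around the network when auto-sizing, mm.
#' @param origin_mm Coordinate of voxel (1,1,1) centre; computed when `NULL`.
#' @return A `phantom_model` with labels 0 = bulk, 1 = duct, and attributes
#'   `origin_mm` stored for coordinate lookups.
#' @export
make_duct_phantom <- function(spec, shape = NULL, pitch_um = c(25, 25, 25),
                              bulk_material = duct_bulk_material(),
                              margin_mm = 1.5, origin_mm = NULL) {
  stopifnot(inherits(spec, "duct_network_spec"))
  pitch_mm <- pitch_um / 1000
  for (seg in spec$segments)
    if (seg$diameter_mm / 2 < max(pitch_mm))
      stop(sprintf("duct radius %g mm below voxel pitch: unresolvable",
                   seg$diameter_mm / 2))
  if (length(spec$segments) > 0L) {
    pts <- do.call(rbind, lapply(spec$segments, `[[`, "points"))
    rmax <- max(vapply(spec$segments, function(s) s$diameter_mm / 2,
                       numeric(1)))
    lo <- apply(pts, 2, min) - rmax - margin_mm
    hi <- apply(pts, 2, max) + rmax + margin_mm
  } else {
    lo <- c(0, 0, 0); hi <- c(1, 1, 1)
  }
  if (is.null(origin_mm)) origin_mm <- lo
  if (is.null(shape))
    shape <- pmax(as.integer(ceiling((hi - origin_mm) / pitch_mm)) + 1L, 2L)
  if (length(spec$segments) > 0L) {
    outside <- pts < matrix(origin_mm, nrow(pts), 3, byrow = TRUE) |
      pts > matrix(origin_mm + (shape - 1) * pitch_mm, nrow(pts), 3,
                   byrow = TRUE)
    if (any(outside)) stop("duct network does not fit inside the grid")
  }

  labels <- array(DUCT_LABELS[["bulk"]], dim = shape)
  for (seg in spec$segments) {
    r <- seg$diameter_mm / 2
    p <- seg$points
    for (i in seq_len(nrow(p) - 1L)) {
      a <- p[i, ]; b <- p[i + 1L, ]
      # restrict to the segment's bounding box plus radius
      lo_i <- pmin(a, b) - r; hi_i <- pmax(a, b) + r
      i0 <- pmax(1L, floor((lo_i - origin_mm) / pitch_mm) + 1L)
      i1 <- pmin(shape, ceiling((hi_i - origin_mm) / pitch_mm) + 1L)
      if (any(i0 > i1)) next
      xs <- origin_mm[1] + (seq(i0[1], i1[1]) - 1) * pitch_mm[1]
      ys <- origin_mm[2] + (seq(i0[2], i1[2]) - 1) * pitch_mm[2]
      zs <- origin_mm[3] + (seq(i0[3], i1[3]) - 1) * pitch_mm[3]
      inside <- segment_tube_inside_grid(a, b, xs, ys, zs, r)
      sub <- labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
      sub[inside] <- DUCT_LABELS[["duct"]]
      labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
    }
  }
  duct_mat <- if (spec$fill == "fluid") spec$fluid_material else
    duct_void_material()
  mats <- stats::setNames(list(bulk_material, duct_mat),
                          as.character(DUCT_LABELS))
  ph <- phantom_model(labels, mats, pitch_um)
  ph$origin_mm <- origin_mm
  ph$duct_spec <- spec
  ph
}

#' Measure duct diameter from the rasterized mask
#'
#' Samples the voxel mask along a line perpendicular to the centerline (in
#' the duct plane) at the requested arc-length fractions and returns the
#' width of the contiguous duct run through the centerline point.
#'
#' @param phantom A duct `phantom_model` from [make_duct_phantom()].
#' @param segment Index of the segment in the phantom's duct spec.
#' @param fractions Arc-length fractions at which to measure.
#' @return Mean measured diameter in mm (attribute `widths_mm` holds each).
#' @export
measure_duct_diameter <- function(phantom, segment = 2L,
                                  fractions = c(0.3, 0.5, 0.7)) {
  spec <- phantom$duct_spec
  if (is.null(spec)) stop("phantom carries no duct network spec")
  seg <- spec$segments[[segment]]
  p <- seg$points
  arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- arc[length(arc)]
  pitch_mm <- phantom$pitch_um / 1000
  origin <- phantom$origin_mm
  step <- min(pitch_mm[1:2]) / 5
  widths <- vapply(fractions, function(f) {
    s <- f * total
    i <- max(which(arc <= s))
    i <- min(i, nrow(p) - 1L)
    t <- (s - arc[i]) / (arc[i + 1L] - arc[i])
    centre <- p[i, ] + t * (p[i + 1L, ] - p[i, ])
    tang <- p[i + 1L, ] - p[i, ]
    tang <- tang / sqrt(sum(tang^2))
    perp <- c(-tang[2], tang[1], 0)
    offs <- seq(-seg$diameter_mm, seg$diameter_mm, by = step)
    inside <- vapply(offs, function(o) {
      q <- centre + o * perp
      idx <- round((q - origin) / pitch_mm) + 1L
      if (any(idx < 1L) || any(idx > dim(phantom$labels))) return(FALSE)
      phantom$labels[idx[1], idx[2], idx[3]] == DUCT_LABELS[["duct"]]
    }, logical(1))
    # contiguous run containing the centre sample
    mid <- which.min(abs(offs))
    if (!inside[mid]) return(0)
    lo <- mid; while (lo > 1L && inside[lo - 1L]) lo <- lo - 1L
    hi <- mid; while (hi < length(offs) && inside[hi + 1L]) hi <- hi + 1L
    (hi - lo + 1L) * step
  }, numeric(1))
  structure(mean(widths), widths_mm = widths)
}
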