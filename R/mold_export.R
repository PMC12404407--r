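# Printable mold geometry as triangle meshes: mask extrusion (staircase
# pixel-boundary contours, exactly countable volume), cylindrical mold walls,
# swept duct tubes, and binary STL interchange. Meshes are vertex/face lists
# in mm; every emitted mesh is watertight (each undirected edge shared by
# exactly two faces) and consistently oriented (each directed edge used
# exactly once), possibly as several closed components.

#' Triangle mesh container
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3L,
            is.matrix(faces), ncol(faces) == 3L)
  if (nrow(faces) == 0L) stop("empty mesh")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  storage.mode(faces) <- "integer"
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, volume %.4g mm^3%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x),
              if (is_watertight(x)) ", watertight" else " (NOT watertight)"))
  invisible(x)
}

#' Signed mesh volume by the divergence theorem
#' @param mesh A [triangle_mesh()].
#' @return Volume in mm^3 (positive for outward-oriented closed meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Watertightness and orientation check
#'
#' @param mesh A [triangle_mesh()].
#' @return `TRUE` when every undirected edge is shared by exactly two faces
#'   and every directed edge appears exactly once (consistent orientation).
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  directed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  keys <- paste(directed[, 1], directed[, 2])
  if (anyDuplicated(keys)) return(FALSE)
  rev_keys <- paste(directed[, 2], directed[, 1])
  all(rev_keys %in% keys)
}

#' Extrude a binary mask into a prism mesh
#'
#' Builds the staircase (pixel-boundary) prism over the mask: top and bottom
#' faces per foreground pixel and side walls wherever a foreground pixel
#' borders background, with vertices shared on the pixel-corner grid. The
#' enclosed volume is exactly `n_pixels * dx * dy * height`.
#'
#' @param mask Logical matrix (must contain at least one foreground pixel).
#' @param pitch_um Pixel pitch (dx, dy) in micrometres.
#' @param height_mm Extrusion height in mm (> 0).
#' @param z0_mm Base plane z, mm.
#' @return A `triangle_mesh` (z-up, outward-oriented).
#' @export
extrude_mask <- function(mask, pitch_um = c(20, 20), height_mm = 1,
                         z0_mm = 0) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask: nothing to extrude")
  if (height_mm <= 0) stop("height_mm must be positive")
  dx <- pitch_um[1] / 1000; dy <- pitch_um[2] / 1000
  nr <- nrow(mask); nc <- ncol(mask)
  inb <- function(i, j) i >= 1L & i <= nr & j >= 1L & j <= nc
  fg <- function(i, j) inb(i, j) && mask[i, j]

  # Vertices live on the (nr+1) x (nc+1) corner grid, but a corner where two
  # foreground pixels touch only diagonally (checkerboard configuration) is
  # split into one vertex per edge-connected fan of foreground pixels around
  # it; otherwise the two diagonal prisms would share a non-manifold edge.
  # The fan is identified by the smallest quadrant index it contains, in the
  # cyclic order (ci-1,cj-1), (ci,cj-1), (ci,cj), (ci-1,cj).
  corner_fan <- function(ci, cj, qi) {
    qs <- rbind(c(ci - 1L, cj - 1L), c(ci, cj - 1L), c(ci, cj),
                c(ci - 1L, cj))
    f <- vapply(1:4, function(q) fg(qs[q, 1], qs[q, 2]), logical(1))
    # connected components under cyclic adjacency
    comp <- integer(4)
    lab <- 0L
    for (s in 1:4) {
      if (!f[s] || comp[s] != 0L) next
      lab <- lab + 1L
      q <- s
      repeat {
        comp[q] <- lab
        nq <- q %% 4L + 1L
        if (f[nq] && comp[nq] == 0L) q <- nq else break
      }
    }
    # wrap-around: merge last fan into first if quadrants 4 and 1 connect
    if (f[1] && f[4] && comp[4] != comp[1]) comp[comp == comp[4]] <- comp[1]
    min(which(comp == comp[qi]))
  }

  vid_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  n_vert <- 0L
  vat <- function(ci, cj, lvl, qi) {
    fan <- corner_fan(ci, cj, qi)
    key <- paste(ci, cj, lvl, fan)
    id <- vid_env[[key]]
    if (is.null(id)) {
      n_vert <<- n_vert + 1L
      id <- n_vert
      vid_env[[key]] <- id
      verts[[id]] <<- c((ci - 1L) * dx, (cj - 1L) * dy,
                        z0_mm + lvl * height_mm)
    }
    id
  }

  faces <- list()
  add_quad <- function(k1, k2, k3, k4) {
    faces[[length(faces) + 1L]] <<- rbind(c(k1, k2, k3), c(k1, k3, k4))
  }
  px <- which(mask, arr.ind = TRUE)
  bg <- function(i, j) !inb(i, j) || !mask[i, j]
  for (r in seq_len(nrow(px))) {
    i <- px[r, 1]; j <- px[r, 2]
    # quadrant index of pixel (i, j) around each of its four corners
    c00b <- vat(i, j, 0L, 3L); c00t <- vat(i, j, 1L, 3L)
    c10b <- vat(i + 1L, j, 0L, 4L); c10t <- vat(i + 1L, j, 1L, 4L)
    c11b <- vat(i + 1L, j + 1L, 0L, 1L); c11t <- vat(i + 1L, j + 1L, 1L, 1L)
    c01b <- vat(i, j + 1L, 0L, 2L); c01t <- vat(i, j + 1L, 1L, 2L)
    add_quad(c00t, c10t, c11t, c01t)            # top (+z)
    add_quad(c00b, c01b, c11b, c10b)            # bottom (-z)
    if (bg(i - 1L, j)) add_quad(c00b, c00t, c01t, c01b)   # -x wall
    if (bg(i + 1L, j)) add_quad(c10b, c11b, c11t, c10t)   # +x wall
    if (bg(i, j - 1L)) add_quad(c00b, c10b, c10t, c00t)   # -y wall
    if (bg(i, j + 1L)) add_quad(c01b, c01t, c11t, c11b)   # +y wall
  }
  triangle_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

# closed surface of revolution solids -------------------------------------

# ring of n vertices at radius r, height z
ring_vertices <- function(r, z, n) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(th), r * sin(th), z)
}

# quad band between two rings of equal size (ids a[], b[]), outward given
# by winding order of the caller
band_faces <- function(a, b) {
  n <- length(a)
  nxt <- c(2:n, 1L)
  rbind(cbind(a, b, b[nxt]), cbind(a, b[nxt], a[nxt]))
}

# fan of triangles from ring ids to a centre id
fan_faces <- function(ring, centre, up = TRUE) {
  n <- length(ring)
  nxt <- c(2:n, 1L)
  if (up) cbind(centre, ring, ring[nxt]) else cbind(centre, ring[nxt], ring)
}

# flip face winding if the (consistently oriented) closed mesh points inward
ensure_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Closed cylinder solid mesh
#' @param radius_mm,z0_mm,z1_mm Geometry (z1 > z0).
#' @param n_theta Angular resolution (default 360 = 1 degree).
#' @return A `triangle_mesh`.
#' @export
cylinder_mesh <- function(radius_mm, z0_mm, z1_mm, n_theta = 360) {
  if (z1_mm <= z0_mm) stop("z1_mm must exceed z0_mm")
  rb <- ring_vertices(radius_mm, z0_mm, n_theta)
  rt <- ring_vertices(radius_mm, z1_mm, n_theta)
  verts <- rbind(rb, rt, c(0, 0, z0_mm), c(0, 0, z1_mm))
  ib <- seq_len(n_theta); it <- n_theta + ib
  cb <- 2L * n_theta + 1L; ct <- 2L * n_theta + 2L
  faces <- rbind(band_faces(ib, it),
                 fan_faces(ib, cb, up = TRUE),
                 fan_faces(it, ct, up = FALSE))
  ensure_outward(triangle_mesh(verts, faces))
}

#' Closed annular (tube-section) solid mesh
#'
#' Solid between inner radius `r_in` and outer radius `r_out` from `z0` to
#' `z1`, closed by flat annulus caps.
#'
#' @param r_in_mm,r_out_mm Inner/outer radii (0 < r_in < r_out).
#' @param z0_mm,z1_mm Axial extent.
#' @param n_theta Angular resolution.
#' @return A `triangle_mesh`.
#' @export
annulus_mesh <- function(r_in_mm, r_out_mm, z0_mm, z1_mm, n_theta = 360) {
  if (!(r_out_mm > r_in_mm && r_in_mm > 0)) stop("need 0 < r_in < r_out")
  if (z1_mm <= z0_mm) stop("z1_mm must exceed z0_mm")
  v <- rbind(ring_vertices(r_out_mm, z0_mm, n_theta),
             ring_vertices(r_out_mm, z1_mm, n_theta),
             ring_vertices(r_in_mm, z0_mm, n_theta),
             ring_vertices(r_in_mm, z1_mm, n_theta))
  ob <- seq_len(n_theta); ot <- n_theta + ob
  ib <- 2L * n_theta + ob; it <- 3L * n_theta + ob
  faces <- rbind(band_faces(ob, ot),            # outer wall (outward)
                 band_faces(it, ib),            # inner wall (inward normal)
                 band_faces(ot, it),            # top annulus cap
                 band_faces(ib, ob))            # bottom annulus cap
  ensure_outward(triangle_mesh(v, faces))
}

#' Cylindrical mold wall around a central structure
#'
#' The printed mold base: a base plate disc plus an annular wall enclosing a
#' hollow cylindrical space (default diameter 45 mm). With the default 1 mm
#' central structure height and 1.2 mm cavity height, the wall leaves a
#' 0.2 mm clearance above the structure for the silicone cover layer. The
#' result is the concatenation of two closed components (plate and wall);
#' overlap with the supplied central region's bounding box is refused.
#'
#' @param mesh_region Optional `triangle_mesh` of the central structure (used
#'   for the containment check), or `NULL`.
#' @param diameter_mm Cavity diameter (default 45).
#' @param height_mm Cavity (wall) height above the base (default 1.2).
#' @param base_thickness_mm Base plate thickness (default 1).
#' @param wall_thickness_mm Radial wall thickness (default 2).
#' @param n_theta Angular resolution (default 360).
#' @return A `triangle_mesh` with two closed components.
#' @export
add_cylindrical_wall <- function(mesh_region = NULL, diameter_mm = 45,
                                 height_mm = 1.2, base_thickness_mm = 1,
                                 wall_thickness_mm = 2, n_theta = 360) {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  if (height_mm <= 0) stop("height_mm must be positive")
  r_in <- diameter_mm / 2
  r_out <- r_in + wall_thickness_mm
  if (!is.null(mesh_region)) {
    v <- mesh_region$vertices
    rad <- sqrt((v[, 1] - mean(range(v[, 1])))^2 +
                (v[, 2] - mean(range(v[, 2])))^2)
    # centre the check on the region's own bounding-box centre
    if (max(rad) > r_in)
      stop("central region exceeds the cavity diameter")
    if (max(v[, 3]) - min(v[, 3]) > height_mm)
      stop("central region exceeds the cavity height")
  }
  base <- cylinder_mesh(r_out, -base_thickness_mm, 0, n_theta)
  wall <- annulus_mesh(r_in, r_out, 0, height_mm, n_theta)
  mesh_concat(list(base, wall))
}

#' Concatenate closed mesh components
#'
#' Boolean-free union: components are appended with reindexed faces after a
#' pairwise axis-aligned bounding-box overlap check (the molds are
#' non-overlapping by construction; refuse otherwise unless `force`).
#'
#' @param meshes List of `triangle_mesh`.
#' @param force Skip the overlap check.
#' @param skip_check Pairs exempt from the bbox check (list of c(i, j)).
#' @return A `triangle_mesh`.
#' @export
mesh_concat <- function(meshes, force = FALSE, skip_check = list()) {
  if (!force && length(meshes) > 1L) {
    skip <- vapply(skip_check, paste, collapse = "-", FUN.VALUE = "")
    for (i in seq_along(meshes)[-length(meshes)])
      for (j in (i + 1L):length(meshes)) {
        if (paste(c(i, j), collapse = "-") %in% skip) next
        if (bbox_overlap(meshes[[i]], meshes[[j]]))
          stop(sprintf("components %d and %d overlap; use force = TRUE", i, j))
      }
  }
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  faces <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$faces + offs[i]))
  triangle_mesh(verts, faces)
}

bbox_overlap <- function(m1, m2, tol = 1e-9) {
  b1 <- apply(m1$vertices, 2, range)
  b2 <- apply(m2$vertices, 2, range)
  all(b1[1, ] < b2[2, ] - tol & b2[1, ] < b1[2, ] - tol)
}

#' Sweep a hollow tube mesh along a duct network
#'
#' For each segment, sweeps an annular cross-section (inner radius = duct
#' radius, outer radius = duct radius + `wall_thickness_mm`, default 0.5 mm)
#' along the centerline polyline using parallel-transported frames, closed by
#' annulus caps at both ends. Optionally concatenates a hollow-disc shell
#' (default diameter 30 mm) around the network; the tube must fit inside the
#' disc cavity (checked analytically).
#'
#' @param spec A [duct_network_spec()].
#' @param wall_thickness_mm Tube wall thickness (default 0.5).
#' @param disc_diameter_mm Shell diameter; `NA` omits the shell.
#' @param disc_cavity_mm Shell interior height (default 3).
#' @param disc_wall_mm Shell plate/rim thickness (default 0.5).
#' @param n_theta Angular resolution of the tube cross-section.
#' @return A `triangle_mesh`.
#' @export
sweep_duct_tube <- function(spec, wall_thickness_mm = 0.5,
                            disc_diameter_mm = 30, disc_cavity_mm = 3,
                            disc_wall_mm = 0.5, n_theta = 48) {
  stopifnot(inherits(spec, "duct_network_spec"))
  if (wall_thickness_mm <= 0) stop("wall_thickness_mm must be positive")
  tubes <- lapply(seq_along(spec$segments), function(si) {
    seg <- spec$segments[[si]]
    swept_tube(seg$points, seg$diameter_mm / 2,
               seg$diameter_mm / 2 + wall_thickness_mm, n_theta,
               seg_name = if (!is.null(seg$name)) seg$name else
                 as.character(si))
  })
  tube_mesh <- mesh_concat(tubes, force = TRUE)   # branches touch the main
  if (is.na(disc_diameter_mm)) return(tube_mesh)
  r_disc <- disc_diameter_mm / 2
  v <- tube_mesh$vertices
  if (max(sqrt(v[, 1]^2 + v[, 2]^2)) > r_disc ||
      max(abs(v[, 3])) > disc_cavity_mm / 2)
    stop("duct tube does not fit inside the disc cavity")
  h <- disc_cavity_mm / 2
  shell <- list(
    cylinder_mesh(r_disc + disc_wall_mm, -h - disc_wall_mm, -h),  # bottom
    cylinder_mesh(r_disc + disc_wall_mm, h, h + disc_wall_mm),    # top
    annulus_mesh(r_disc, r_disc + disc_wall_mm, -h, h))           # rim
  mesh_concat(c(list(tube_mesh), shell), force = TRUE)
}

# hollow tube (annular cross-section) swept along a polyline with
# parallel-transported frames; refuses self-intersecting sharp bends
swept_tube <- function(points, r_in, r_out, n_theta, seg_name = "segment") {
  n <- nrow(points)
  tangents <- rbind(points[2, ] - points[1, ],
                    (points[min(3, n):n, , drop = FALSE] -
                       points[seq_len(n - 2), , drop = FALSE]) / 2,
                    points[n, ] - points[n - 1, ])
  if (n == 2) tangents <- rbind(points[2, ] - points[1, ],
                                points[2, ] - points[1, ])
  tangents <- tangents / sqrt(rowSums(tangents^2))
  # bend check: turning angle small enough that the outer surface cannot
  # self-intersect given the local sample spacing
  if (n > 2) {
    seg_len <- sqrt(rowSums((points[-1, , drop = FALSE] -
                               points[-n, , drop = FALSE])^2))
    cosang <- rowSums(tangents[-n, , drop = FALSE] *
                        tangents[-1, , drop = FALSE])
    ang <- acos(pmin(pmax(cosang, -1), 1))
    bad <- which(tan(ang / 2) * r_out > pmin(seg_len, c(seg_len[-1],
                                                        seg_len[n - 1])))
    if (length(bad) > 0L)
      stop(sprintf("self-intersecting sweep at sharp bend in segment '%s'",
                   seg_name))
  }
  # parallel transport an initial normal along the tangents
  t1 <- tangents[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n0 <- ref - sum(ref * t1) * t1
  n0 <- n0 / sqrt(sum(n0^2))
  normals <- matrix(0, n, 3)
  normals[1, ] <- n0
  for (i in 2:n) {
    ni <- normals[i - 1, ] - sum(normals[i - 1, ] * tangents[i, ]) *
      tangents[i, ]
    normals[i, ] <- ni / sqrt(sum(ni^2))
  }
  binormals <- cbind(
    tangents[, 2] * normals[, 3] - tangents[, 3] * normals[, 2],
    tangents[, 3] * normals[, 1] - tangents[, 1] * normals[, 3],
    tangents[, 1] * normals[, 2] - tangents[, 2] * normals[, 1])
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ring_at <- function(i, r) {
    points[rep(i, n_theta), , drop = FALSE] +
      outer(cos(th), normals[i, ]) * r + outer(sin(th), binormals[i, ]) * r
  }
  verts <- NULL
  out_ids <- in_ids <- matrix(0L, n, n_theta)
  for (i in seq_len(n)) {
    verts <- rbind(verts, ring_at(i, r_out), ring_at(i, r_in))
    out_ids[i, ] <- (i - 1L) * 2L * n_theta + seq_len(n_theta)
    in_ids[i, ] <- (i - 1L) * 2L * n_theta + n_theta + seq_len(n_theta)
  }
  faces <- NULL
  for (i in seq_len(n - 1L)) {
    faces <- rbind(faces,
                   band_faces(out_ids[i, ], out_ids[i + 1L, ]),
                   band_faces(in_ids[i + 1L, ], in_ids[i, ]))
  }
  faces <- rbind(faces,
                 band_faces(in_ids[1, ], out_ids[1, ]),        # start cap
                 band_faces(out_ids[n, ], in_ids[n, ]))        # end cap
  ensure_outward(triangle_mesh(verts, faces))
}

#' Write a triangle mesh as binary STL (mm units)
#'
#' @param mesh A `triangle_mesh`; non-watertight meshes are refused unless
#'   `force = TRUE`.
#' @param path Output path.
#' @param force Write even if the mesh is not watertight.
#' @export
write_stl <- function(mesh, path, force = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!force && !is_watertight(mesh))
    stop("mesh is not watertight; use force = TRUE to write anyway")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("qmephantom binary STL (mm)", width = -80))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # 12 floats per facet: normal, v1, v2, v3
  block <- t(cbind(nrm, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]))
  writeBin(raw(0), con)
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file into a triangle mesh
#'
#' Vertices are deduplicated by exact float32 coordinate match so that
#' watertightness can be re-checked after a round trip.
#'
#' @param path STL path.
#' @return A `triangle_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (nf <= 0) stop("empty or invalid STL")
  tri <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    tri[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  uniq <- !duplicated(key)
  ids <- match(key, key[uniq])
  verts <- tri[uniq, , drop = FALSE]
  faces <- matrix(ids, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}
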