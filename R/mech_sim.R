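# Ground-truth compression mechanics under the same idealization the QME
# reconstruction assumes: uniform, uniaxial stress along each lateral column
# (a series-spring stack), with an explicit, separate emulation of lateral
# mechanical coupling.
#
# Sign conventions: compressive strain is negative. Displacement u is stored
# as the magnitude of motion toward the fixed plate (bottom, largest z), so
# u >= 0, u = 0 at the plate, and du/dz = strain (u decreases with depth).

#' Displacement field container
#' @param u 3D numeric array, axial displacement in micrometres.
#' @param valid 3D logical array.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(u, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(u)
  structure(list(u = u, valid = valid), class = "displacement_field")
}

#' Strain field container
#' @param strain 3D numeric array (unitless, compression negative).
#' @param valid 3D logical array.
#' @return Object of class `strain_field`.
#' @export
strain_field <- function(strain, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(strain)
  structure(list(strain = strain, valid = valid), class = "strain_field")
}

#' Surface stress map container
#' @param stress 2D numeric matrix, axial stress magnitude in kPa.
#' @param valid 2D logical matrix.
#' @return Object of class `stress_map`.
#' @export
stress_map <- function(stress, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(stress)
  if (any(stress[valid] < 0)) stop("stress must be non-negative")
  structure(list(stress = stress, valid = valid), class = "stress_map")
}

#' Solve the per-column surface stress for a bulk pre-strain
#'
#' Under the uniform-uniaxial-stress idealization each lateral column is a
#' stack of springs in series. For a given bulk pre-strain, the stress in a
#' column is the value sigma for which the column's total compression
#' `sum(strain_i(sigma) * dz)` equals `bulk_prestrain x (solid thickness)`.
#' Linear materials give sigma in closed form; a nonlinear layer
#' stress-strain curve is handled by bisection. Void voxels carry no load
#' and are excluded from both the thickness and the compliance of the column
#' (their geometric collapse is not modeled); columns that are entirely void
#' are marked invalid.
#'
#' @param phantom A `phantom_model` (with or without compliant layer).
#' @param bulk_prestrain Unitless compressive bulk strain in (0, 0.5).
#' @return A [stress_map()] of stress magnitudes (kPa).
#' @export
solve_prestrain_stress <- function(phantom, bulk_prestrain) {
  if (bulk_prestrain < 0 || bulk_prestrain >= 0.5)
    stop("bulk_prestrain must be in [0, 0.5)")
  E <- modulus_grid(phantom)
  d <- dim(E)
  dz <- phantom$pitch_um[3]
  dim(E) <- c(d[1] * d[2], d[3])
  solid <- is.finite(E)
  n_solid <- rowSums(solid)
  thickness <- n_solid * dz
  # compliance per column: sum dz / E_i over solid voxels
  invE <- ifelse(solid, 1 / E, 0)
  compliance <- rowSums(invE) * dz
  sigma <- ifelse(compliance > 0,
                  bulk_prestrain * thickness / compliance, NA_real_)
  # nonlinear layer: refine by bisection on the column equation
  if (!is.null(phantom$layer) && !is_linear_curve(phantom$layer)) {
    sigma <- refine_stress_nonlinear(phantom, bulk_prestrain, E, solid,
                                     thickness, sigma)
  }
  stress <- matrix(sigma, d[1], d[2])
  stress_map(stress, valid = matrix(n_solid > 0, d[1], d[2]))
}

is_linear_curve <- function(layer) {
  f <- layer$stress_strain
  s <- f(c(0.02, 0.05, 0.1, 0.16))
  max(abs(s - s[4] / 0.16 * c(0.02, 0.05, 0.1, 0.16))) < 1e-9 * max(abs(s))
}

# bisection on sigma for columns containing the (nonlinear) layer material
refine_stress_nonlinear <- function(phantom, bulk_prestrain, E, solid,
                                    thickness, sigma0) {
  layer_id <- phantom$layer_id
  lab <- phantom$labels
  d <- dim(lab)
  dim(lab) <- c(d[1] * d[2], d[3])
  dz <- phantom$pitch_um[3]
  inv_curve <- function(sig) {
    # strain magnitude at stress sig from the monotone layer curve
    f <- phantom$layer$stress_strain
    vapply(sig, function(s) {
      if (s <= 0) return(0)
      stats::uniroot(function(e) f(e) - s, c(0, 0.2), tol = 1e-12,
                     extendInt = "upX")$root
    }, numeric(1))
  }
  n_cols <- nrow(lab)
  out <- sigma0
  for (j in seq_len(n_cols)) {
    is_layer <- lab[j, ] == layer_id & solid[j, ]
    n_lay <- sum(is_layer)
    if (n_lay == 0L) next
    other <- solid[j, ] & !is_layer
    comp_other <- sum(1 / E[j, other]) * dz
    target <- bulk_prestrain * thickness[j]
    g <- function(s) inv_curve(s) * n_lay * dz + s * comp_other - target
    hi <- max(sigma0[j], 1e-6) * 4
    while (g(hi) < 0) hi <- hi * 2
    out[j] <- stats::uniroot(g, c(0, hi), tol = 1e-10 * max(hi, 1))$root
  }
  out
}

#' Deform a phantom column-by-column under a given surface stress
#'
#' Per lateral column, `strain(z) = -sigma / E(z)` for solid and fluid
#' voxels; void voxels are invalid. Displacement is the cumulative integral
#' of compression from the fixed plate (bottom) upward, with u = 0 at the
#' plate, stored as motion toward the plate (u >= 0, du/dz = strain).
#'
#' @param phantom A `phantom_model`.
#' @param stress A [stress_map()] on the phantom's lateral grid.
#' @return List with elements `disp` ([displacement_field()]) and `strain`
#'   ([strain_field()]).
#' @export
series_spring_deform <- function(phantom, stress) {
  stopifnot(inherits(stress, "stress_map"))
  E <- modulus_grid(phantom)
  d <- dim(E)
  if (!identical(dim(stress$stress), d[1:2]))
    stop("stress map does not match the phantom's lateral grid")
  sig <- array(rep(as.vector(stress$stress), times = d[3]), dim = d)
  strain <- -sig / E                      # NA where void
  strain[rep(!stress$valid, times = d[3])] <- NA_real_
  valid <- is.finite(strain)
  u <- strain_to_displacement(strain_field(strain, valid), phantom$pitch_um)
  list(disp = u, strain = strain_field(strain, valid))
}

#' Integrate a strain field into a displacement field
#'
#' `u(z) = -sum over z' >= z of strain(z') * dz` (invalid voxels contribute
#' zero compression), giving u = 0 at the fixed plate and du/dz = strain.
#'
#' @param strain A [strain_field()].
#' @param pitch_um Voxel pitch (dx, dy, dz) in micrometres.
#' @return A [displacement_field()] in micrometres.
#' @export
strain_to_displacement <- function(strain, pitch_um) {
  s <- strain$strain
  d <- dim(s)
  dz <- pitch_um[3]
  s0 <- ifelse(is.finite(s), s, 0)
  dim(s0) <- c(d[1] * d[2], d[3])
  # reverse cumulative sum along z: u_k = -sum_{j >= k} strain_j * dz
  cum <- s0
  for (k in seq(d[3] - 1L, length.out = max(d[3] - 1L, 0L), by = -1L))
    cum[, k] <- cum[, k + 1L] + s0[, k]
  u <- -cum * dz
  dim(u) <- d
  displacement_field(u, valid = strain$valid)
}

#' Lateral (x-y) Gaussian blur of a strain field
#'
#' Explicit emulation of lateral mechanical coupling: each z-plane is
#' convolved with a normalized Gaussian of the stated full-width at half
#' maximum. Invalid voxels are excluded by renormalizing the kernel mass over
#' valid neighbours, so a constant field is preserved exactly.
#'
#' @param field A [strain_field()].
#' @param kernel_fwhm_um Kernel FWHM in micrometres (0 = identity).
#' @param pitch_um Voxel pitch in micrometres.
#' @return A blurred [strain_field()].
#' @export
lateral_coupling_blur <- function(field, kernel_fwhm_um, pitch_um) {
  if (kernel_fwhm_um < 0) stop("kernel_fwhm_um must be >= 0")
  if (kernel_fwhm_um == 0) return(field)
  s <- field$strain
  d <- dim(s)
  sigma_px <- kernel_fwhm_um / (2 * sqrt(2 * log(2)))
  out <- array(NA_real_, dim = d)
  for (k in seq_len(d[3])) {
    plane <- s[, , k]
    v <- is.finite(plane)
    p0 <- ifelse(v, plane, 0)
    num <- gauss_blur2(p0, sigma_px / pitch_um[1], sigma_px / pitch_um[2])
    den <- gauss_blur2(v * 1, sigma_px / pitch_um[1], sigma_px / pitch_um[2])
    res <- ifelse(den > 1e-12, num / den, NA_real_)
    res[!v] <- NA_real_
    out[, , k] <- res
  }
  strain_field(out, valid = is.finite(out))
}

# separable Gaussian blur of a matrix, kernel truncated at 4 sigma,
# renormalized at the borders (zero-padding handled by callers via the
# valid-mass division)
gauss_blur2 <- function(m, sx, sy) {
  blur1 <- function(mat, s, along) {
    if (s <= 0) return(mat)
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    n <- if (along == 1) nrow(mat) else ncol(mat)
    out <- matrix(0, nrow(mat), ncol(mat))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      if (along == 1) {
        idx <- seq_len(n) + off
        ok <- idx >= 1L & idx <= n
        out[ok, ] <- out[ok, ] + k[i] * mat[idx[ok], ]
      } else {
        idx <- seq_len(n) + off
        ok <- idx >= 1L & idx <= n
        out[, ok] <- out[, ok] + k[i] * mat[, idx[ok]]
      }
    }
    out
  }
  blur1(blur1(m, sx, 1L), sy, 2L)
}
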