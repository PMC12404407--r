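# QME reconstruction chain: complex tomogram pair -> phase difference ->
# displacement -> weighted least-squares strain -> compliant-layer stress ->
# elasticity, plus the standard post-processing (crop, median filter,
# en-face averaging).

#' Phase-sensitive displacement estimation
#'
#' Computes the per-voxel phase difference `arg(loaded * conj(unloaded))`,
#' unwraps it along depth per A-line (nearest-2pi continuity starting from
#' the surface voxel), and converts to displacement
#' `u = lambda0 * dphi / (4 * pi * n)`. Because the surface voxel's absolute
#' phase is only known modulo 2pi, u carries an arbitrary per-A-line offset
#' of multiples of lambda0/(2n); depth gradients (strain) are unaffected.
#' Voxels whose unloaded SNR falls below `snr_gate_db` are marked invalid.
#'
#' @param unloaded,loaded [complex_tomogram()]s with identical metadata.
#' @param snr_gate_db SNR gate in dB (default 5).
#' @return List with `dphi` (list: `dphi` array, `valid`) and `disp`
#'   ([displacement_field()], micrometres).
#' @export
phase_difference_displacement <- function(unloaded, loaded, snr_gate_db = 5) {
  stopifnot(inherits(unloaded, "complex_tomogram"),
            inherits(loaded, "complex_tomogram"))
  if (!identical(unloaded$meta[c("lambda0_nm", "refr_index", "pitch_um")],
                 loaded$meta[c("lambda0_nm", "refr_index", "pitch_um")]))
    stop("tomogram metadata mismatch")
  if (!identical(dim(unloaded$field), dim(loaded$field)))
    stop("tomogram grids differ")
  d <- dim(unloaded$field)
  dphi <- Arg(loaded$field * Conj(unloaded$field))
  dim(dphi) <- c(d[1] * d[2], d[3])
  # depth unwrap: keep increments in (-pi, pi]
  if (d[3] > 1L) {
    for (k in 2:d[3]) {
      step <- dphi[, k] - dphi[, k - 1L]
      step <- step - 2 * pi * round(step / (2 * pi))
      dphi[, k] <- dphi[, k - 1L] + step
    }
  }
  dim(dphi) <- d
  valid <- snr_db(unloaded) >= snr_gate_db
  u <- dphi / phase_per_um(unloaded$meta)
  list(dphi = list(dphi = dphi, valid = valid),
       disp = displacement_field(u, valid))
}

#' Weighted least-squares strain over a depth fitting range
#'
#' At each voxel, the local axial strain is the slope of a weighted
#' least-squares line fit of displacement versus depth over a centred window
#' spanning `fit_range_um` (windows are clipped at the volume edges). Weights
#' default to the linear-scale OCT SNR of the unloaded tomogram (phase noise
#' variance scales as 1/SNR). Voxels with fewer than 3 valid samples in the
#' window, or with no weight mass, are invalid.
#'
#' @param disp A [displacement_field()] (micrometres).
#' @param weights 3D array of non-negative weights (negative values are
#'   treated as zero); `NULL` for uniform weights.
#' @param fit_range_um Fitting range in micrometres (must span >= 3 samples).
#' @param pitch_um Voxel pitch in micrometres.
#' @return A [strain_field()] (unitless, compression negative).
#' @export
wls_strain <- function(disp, weights = NULL, fit_range_um = 100,
                       pitch_um) {
  u <- disp$u
  d <- dim(u)
  dz <- pitch_um[3]
  win <- round(fit_range_um / dz)
  if (win < 3) stop("fit_range_um must span at least 3 axial samples")
  half_lo <- (win - 1L) %/% 2L
  half_hi <- win - 1L - half_lo
  if (is.null(weights)) weights <- array(1, dim = d)
  w <- weights
  w[w < 0] <- 0
  w[!disp$valid] <- 0
  u0 <- ifelse(disp$valid, u, 0)

  # z coordinate centred on the volume middle for numerical conditioning
  z <- (seq_len(d[3]) - (d[3] + 1) / 2) * dz
  nl <- d[1] * d[2]
  dim(w) <- c(nl, d[3]); dim(u0) <- c(nl, d[3])

  wins <- function(m) {
    # sliding-window sums along z via cumulative sums, clipped at edges
    cs <- m
    for (k in seq_len(d[3])[-1L]) cs[, k] <- cs[, k - 1L] + m[, k]
    lo <- pmax(seq_len(d[3]) - half_lo, 1L)
    hi <- pmin(seq_len(d[3]) + half_hi, d[3])
    out <- cs[, hi, drop = FALSE]
    has_prev <- lo > 1L
    out[, has_prev] <- out[, has_prev] - cs[, lo[has_prev] - 1L]
    out
  }
  zrep <- rep(z, each = nl)               # column-major expansion of z
  S0 <- wins(w)
  S1 <- wins(w * zrep)
  S2 <- wins(w * zrep * zrep)
  T0 <- wins(w * u0)
  T1 <- wins(w * zrep * u0)
  nv <- wins((w > 0) * 1)
  det <- S0 * S2 - S1 * S1
  slope <- (S0 * T1 - S1 * T0) / det
  bad <- nv < 3 | S0 <= 0 | abs(det) < 1e-300
  slope[bad] <- NA_real_
  dim(slope) <- d
  strain_field(slope, valid = is.finite(slope))
}

#' Surface stress from the compliant-layer strain
#'
#' At each lateral position the layer strain is taken as the mean valid
#' strain over the layer's axial extent just above the layer-sample
#' interface, excluding a margin at both layer boundaries where the strain
#' fitting window straddles an interface; the pre-characterized stress-strain
#' curve then gives the axial stress magnitude at the sample surface.
#'
#' @param strain A [strain_field()].
#' @param layer A [compliant_layer()].
#' @param interface_z Index of the last layer plane.
#' @param pitch_um Voxel pitch in micrometres.
#' @param margin_planes Planes excluded at each end of the layer extent
#'   (default: half the 100 um fitting window at the grid's dz).
#' @return A [stress_map()] (kPa).
#' @export
layer_stress <- function(strain, layer, interface_z, pitch_um,
                         margin_planes = NULL) {
  d <- dim(strain$strain)
  if (interface_z < 1L || interface_z > d[3])
    stop("interface_z outside the grid")
  n_layer <- round(layer$thickness_um / pitch_um[3])
  z0 <- max(1L, interface_z - n_layer + 1L)
  if (is.null(margin_planes))
    margin_planes <- min((round(100 / pitch_um[3]) + 1L) %/% 2L,
                         max((interface_z - z0) %/% 3L, 0L))
  lo <- z0 + margin_planes
  hi <- interface_z - margin_planes
  if (lo > hi) { lo <- z0; hi <- interface_z }
  sub <- strain$strain[, , lo:hi, drop = FALSE]
  mean_strain <- apply(sub, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  stress <- matrix(NA_real_, d[1], d[2])
  ok <- is.finite(mean_strain)
  stress[ok] <- vapply(abs(mean_strain[ok]), layer$stress_strain, numeric(1))
  stress_map(stress, valid = ok)
}

#' Elastogram container
#' @param elasticity 3D numeric array, kPa (> 0 where valid); displayed on a
#'   log scale by convention.
#' @param valid 3D logical array.
#' @return Object of class `elastogram`.
#' @export
elastogram <- function(elasticity, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(elasticity)
  structure(list(elasticity = elasticity, valid = valid),
            class = "elastogram")
}

#' Elasticity map: local stress over local strain
#'
#' `E(x, y, z) = stress(x, y) / |strain(x, y, z)|` under the assumption of
#' uniform, uniaxial stress in depth. Strain magnitudes below `strain_floor`
#' give invalid (masked) voxels rather than infinities.
#'
#' @param stress A [stress_map()] (kPa).
#' @param strain A [strain_field()].
#' @param strain_floor Minimum |strain| (default 1e-5).
#' @return An [elastogram()] in kPa.
#' @export
elasticity_map <- function(stress, strain, strain_floor = 1e-5) {
  d <- dim(strain$strain)
  if (!identical(dim(stress$stress), d[1:2]))
    stop("stress and strain lateral grids differ")
  sm <- abs(strain$strain)
  sig <- array(rep(as.vector(stress$stress), times = d[3]), dim = d)
  E <- sig / sm
  E[sm < strain_floor] <- NA_real_
  E[rep(!stress$valid, times = d[3])] <- NA_real_
  E[!strain$valid] <- NA_real_
  elastogram(E, valid = is.finite(E))
}

#' Crop, median-filter and en-face average a reconstructed volume
#'
#' Standard elastogram post-processing: centre-crop in x-y, per-plane k x k
#' median filtering, then averaging over a depth range starting at `at_z`
#' (invalid voxels are ignored). The filter/average order can be swapped.
#'
#' @param volume 3D numeric array (NA = invalid).
#' @param crop_px Length-2 (width, height) centre crop, or `NULL` to skip.
#' @param median_px Odd median-filter kernel size (1 = no filtering).
#' @param enface_depth_um Depth range to average over, micrometres.
#' @param at_z First z index of the averaging range.
#' @param pitch_um Voxel pitch in micrometres.
#' @param order `"filter_then_average"` (default) or `"average_then_filter"`.
#' @return 2D numeric matrix (the en-face image).
#' @export
postprocess_enface <- function(volume, crop_px = NULL, median_px = 3,
                               enface_depth_um = 100, at_z = 1L, pitch_um,
                               order = c("filter_then_average",
                                         "average_then_filter")) {
  order <- match.arg(order)
  d <- dim(volume)
  if (!is.null(crop_px)) {
    if (crop_px[1] > d[1] || crop_px[2] > d[2])
      stop("crop larger than volume")
    x0 <- (d[1] - crop_px[1]) %/% 2L
    y0 <- (d[2] - crop_px[2]) %/% 2L
    volume <- volume[x0 + seq_len(crop_px[1]), y0 + seq_len(crop_px[2]), ,
                     drop = FALSE]
    d <- dim(volume)
  }
  n_planes <- max(1L, round(enface_depth_um / pitch_um[3]))
  zs <- at_z:min(at_z + n_planes - 1L, d[3])
  planes <- volume[, , zs, drop = FALSE]
  if (order == "filter_then_average") {
    for (i in seq_along(zs))
      planes[, , i] <- median_filter2(planes[, , i], median_px)
    enface_mean(planes)
  } else {
    median_filter2(enface_mean(planes), median_px)
  }
}

enface_mean <- function(planes) {
  n <- rowSums(!is.na(planes), dims = 2L)
  s <- rowSums(planes, na.rm = TRUE, dims = 2L)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

#' k x k median filter of a matrix (NA-aware, edge-clipped windows)
#'
#' @param m Numeric matrix.
#' @param k Odd kernel size; `k = 1` returns the input.
#' @return Filtered matrix.
#' @export
median_filter2 <- function(m, k = 3) {
  if (k <= 1L) return(m)
  if (k %% 2 == 0) stop("median filter size must be odd")
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  # gather the k^2 shifted copies (edge-replicated), then row-wise medians
  stack <- array(NA_real_, dim = c(nr * nc, k * k))
  idx <- 1L
  for (dx in -r:r) {
    ri <- pmin(pmax(seq_len(nr) + dx, 1L), nr)
    for (dy in -r:r) {
      ci <- pmin(pmax(seq_len(nc) + dy, 1L), nc)
      stack[, idx] <- as.vector(m[ri, ci])
      idx <- idx + 1L
    }
  }
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  matrix(med, nr, nc)
}

#' Full QME reconstruction from a tomogram pair
#'
#' Convenience driver chaining [phase_difference_displacement()],
#' [wls_strain()] (weighted by the unloaded linear SNR), [layer_stress()]
#' and [elasticity_map()].
#'
#' @param unloaded,loaded [complex_tomogram()]s.
#' @param layer The [compliant_layer()] on top of the sample.
#' @param interface_z Index of the last layer plane.
#' @param fit_range_um Strain fitting range (default 100 um).
#' @param snr_gate_db SNR validity gate (default 5 dB).
#' @param strain_floor Minimum |strain| for elasticity (default 1e-5).
#' @return List with `disp`, `strain`, `stress`, `elast`.
#' @export
qme_reconstruct <- function(unloaded, loaded, layer, interface_z,
                            fit_range_um = 100, snr_gate_db = 5,
                            strain_floor = 1e-5) {
  pd <- phase_difference_displacement(unloaded, loaded, snr_gate_db)
  weights <- 10^(snr_db(unloaded) / 10)
  strain <- wls_strain(pd$disp, weights, fit_range_um,
                       unloaded$meta$pitch_um)
  stress <- layer_stress(strain, layer, interface_z, unloaded$meta$pitch_um)
  elast <- elasticity_map(stress, strain, strain_floor)
  list(disp = pd$disp, strain = strain, stress = stress, elast = elast)
}
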