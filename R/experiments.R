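# End-to-end studies: simulate a phantom under compression, image it,
# reconstruct the elastogram, and analyze region statistics and boundary
# step responses. These drivers are what the analysis scripts and the
# acceptance harness call.

#' Experiment configuration
#'
#' The static bulk pre-strain (default 5%) sets the mechanical operating
#' point; the loaded/unloaded tomogram pair encodes a small actuator
#' increment (`actuation_strain`, default 0.1% bulk strain, the microscale
#' compression of the ring actuator) so that per-voxel phase increments stay
#' far below the 2*pi wrapping limit. For linear materials the recovered
#' modulus is independent of the increment size.
#'
#' @param seed Integer seed (required).
#' @param prestrain Bulk pre-strain in (0, 0.2) (default 0.05).
#' @param actuation_strain Bulk strain increment encoded in the tomogram
#'   pair (default 0.001).
#' @param meta An [acquisition_meta()].
#' @param layer A [compliant_layer()].
#' @param fit_range_um Strain fitting range (default 100).
#' @param snr_gate_db SNR validity gate (default 5).
#' @param strain_floor Elasticity strain floor (default 1e-5).
#' @param median_px En-face median filter size (default 3).
#' @param enface_depth_um En-face averaging depth (default 100).
#' @param coupling_fwhm_um Lateral mechanical-coupling blur FWHM (0 = off).
#' @param noiseless Use a noise-free tomogram pair.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(seed, prestrain = 0.05,
                              actuation_strain = 0.001,
                              meta = acquisition_meta(),
                              layer = compliant_layer(),
                              fit_range_um = 100, snr_gate_db = 5,
                              strain_floor = 1e-5, median_px = 3,
                              enface_depth_um = 100,
                              coupling_fwhm_um = 0, noiseless = FALSE) {
  if (missing(seed)) stop("seed must be set explicitly")
  if (prestrain <= 0 || prestrain >= 0.2)
    stop("prestrain must be in (0, 0.2)")
  structure(list(seed = as.integer(seed), prestrain = prestrain,
                 actuation_strain = actuation_strain, meta = meta,
                 layer = layer, fit_range_um = fit_range_um,
                 snr_gate_db = snr_gate_db, strain_floor = strain_floor,
                 median_px = median_px, enface_depth_um = enface_depth_um,
                 coupling_fwhm_um = coupling_fwhm_um,
                 noiseless = isTRUE(noiseless)),
            class = "experiment_config")
}

#' Simulate and reconstruct one phantom
#'
#' Chains the forward model (layer attachment, pre-strain stress solve,
#' series-spring deformation at the actuation increment, optional lateral
#' coupling blur, correlated speckle pair) and the QME reconstruction.
#'
#' @param phantom A `phantom_model` without layer (the config's layer is
#'   attached here).
#' @param config An [experiment_config()].
#' @return List with `phantom` (layered), `truth` (list: stress, strain,
#'   disp at the actuation increment) and the [qme_reconstruct()] outputs.
#' @export
simulate_and_reconstruct <- function(phantom, config) {
  ph <- attach_layer(phantom, config$layer)
  meta <- config$meta
  meta$pitch_um <- ph$pitch_um
  stress_act <- solve_prestrain_stress(ph, config$actuation_strain)
  mech <- series_spring_deform(ph, stress_act)
  strain_true <- mech$strain
  if (config$coupling_fwhm_um > 0)
    strain_true <- lateral_coupling_blur(strain_true,
                                         config$coupling_fwhm_um,
                                         ph$pitch_um)
  disp <- strain_to_displacement(strain_true, ph$pitch_um)
  pair <- oct_pair(ph, meta, disp, config$seed,
                   noiseless = config$noiseless)
  recon <- qme_reconstruct(pair$unloaded, pair$loaded, config$layer,
                           ph$interface_z, config$fit_range_um,
                           config$snr_gate_db, config$strain_floor)
  list(phantom = ph,
       truth = list(stress = stress_act, strain = strain_true, disp = disp),
       unloaded = pair$unloaded,
       disp = recon$disp, strain = recon$strain, stress = recon$stress,
       elast = recon$elast)
}

#' Homogeneous-slab elasticity recovery
#'
#' Builds a flat single-material phantom, runs the full speckle simulation
#' and QME reconstruction, and reports the median reconstructed elasticity
#' over a central lateral region at the sample's mid-depth. Because every
#' step of the forward model and of the reconstruction acts independently on
#' each lateral position, the volume is processed in y-slabs (seeded
#' deterministically from the config seed), which bounds memory without
#' changing the per-column computation.
#'
#' @param youngs_modulus_kpa Ground-truth modulus, kPa.
#' @param backscatter_db Region backscatter (default 30 dB).
#' @param shape Sample grid shape before layer attachment
#'   (default c(256, 256, 300)).
#' @param pitch_um Voxel pitch (default c(15, 15, 3.5)).
#' @param config An [experiment_config()].
#' @param central_px Side length of the central median region (default 128).
#' @param chunk_ny y-slab width (default 32).
#' @return List with `median_kpa`, `truth_kpa`, `mid_z` and `enface_mid`
#'   (the mid-depth elasticity image in kPa).
#' @export
run_recovery_experiment <- function(youngs_modulus_kpa,
                                    backscatter_db = 30,
                                    shape = c(256, 256, 300),
                                    pitch_um = c(15, 15, 3.5),
                                    config = experiment_config(seed = 1),
                                    central_px = 128, chunk_ny = 32) {
  mat <- material_spec("sample", youngs_modulus_kpa, backscatter_db)
  enface_mid <- matrix(NA_real_, shape[1], shape[2])
  mid <- NA_integer_
  y0 <- 0L
  k <- 0L
  while (y0 < shape[2]) {
    ny <- min(chunk_ny, shape[2] - y0)
    k <- k + 1L
    ph <- make_slab_phantom(c(shape[1], ny, shape[3]), mat, pitch_um)
    cfg <- config
    cfg$seed <- config$seed + (k - 1L) * 7919L
    res <- simulate_and_reconstruct(ph, cfg)
    mid <- res$phantom$interface_z + shape[3] %/% 2L
    enface_mid[, y0 + seq_len(ny)] <- res$elast$elasticity[, , mid]
    y0 <- y0 + ny
  }
  cx <- (shape[1] - central_px) %/% 2L
  cy <- (shape[2] - central_px) %/% 2L
  e_mid <- enface_mid[cx + seq_len(central_px), cy + seq_len(central_px)]
  list(median_kpa = stats::median(e_mid, na.rm = TRUE),
       truth_kpa = youngs_modulus_kpa,
       mid_z = mid, enface_mid = enface_mid)
}

#' IDC-phantom experiment: region statistics and boundary resolution
#'
#' Generates (or takes) dense/IDC masks, builds the three-region phantom,
#' simulates and reconstructs, computes per-region elasticity statistics on
#' the structure-depth en-face image, and fits step responses across the
#' stroma-adipose and IDC-stroma boundaries along a horizontal line through
#' the dense blob's centroid.
#'
#' @param config An [experiment_config()].
#' @param masks Optional list with `dense` and `idc` masks; generated from
#'   the config seed when `NULL`.
#' @param shape Lateral shape used when generating masks (default 96 x 96).
#' @param pitch_um Voxel pitch (default c(40, 40, 10)).
#' @param heights_um Section heights passed to [make_idc_phantom()].
#' @param profile_halfwidth_um Half-length of step-response sampling lines.
#' @return List (class `idc_report`) with `region_stats`, `resolution`,
#'   `enface` (strain and elasticity matrices), `labels`, `config`.
#' @export
run_idc_experiment <- function(config, masks = NULL, shape = c(96, 96),
                               pitch_um = c(40, 40, 10),
                               heights_um = c(cover = 100, structure = 600,
                                              base = 300),
                               profile_halfwidth_um = 1200) {
  if (is.null(masks))
    masks <- make_synthetic_masks(shape, pitch_um[1:2], config$seed)
  ph <- make_idc_phantom(masks$dense, masks$idc, heights_um, pitch_um)
  res <- simulate_and_reconstruct(ph, config)
  php <- res$phantom
  z_struct <- php$structure_z
  at_z <- z_struct[ceiling(length(z_struct) / 2)] -
    max(0L, round(config$enface_depth_um / pitch_um[3]) %/% 2L)
  at_z <- max(at_z, z_struct[1])
  enface_strain <- postprocess_enface(res$strain$strain,
                                      median_px = config$median_px,
                                      enface_depth_um = config$enface_depth_um,
                                      at_z = at_z, pitch_um = pitch_um)
  enface_elast <- postprocess_enface(res$elast$elasticity,
                                     median_px = config$median_px,
                                     enface_depth_um = config$enface_depth_um,
                                     at_z = at_z, pitch_um = pitch_um)
  labels <- combine_region_masks(masks$dense, masks$idc)
  region_stats <- do.call(rbind, lapply(
    c(adipose = 0L, stroma = 1L, idc = 2L), function(id) {
      e <- enface_elast[labels == id]
      s <- enface_strain[labels == id]
      data.frame(n_px = sum(labels == id),
                 elast_median_kpa = stats::median(e, na.rm = TRUE),
                 elast_iqr_kpa = stats::IQR(e, na.rm = TRUE),
                 strain_median = stats::median(s, na.rm = TRUE))
    }))
  region_stats <- cbind(region = c("adipose", "stroma", "idc"), region_stats)
  rownames(region_stats) <- NULL

  profiles <- boundary_profiles(enface_strain, enface_elast, labels,
                                pitch_um[1:2], profile_halfwidth_um)
  resolution <- if (length(profiles) > 0L) resolution_report(profiles)
  else NULL
  structure(list(region_stats = region_stats, resolution = resolution,
                 enface = list(strain = enface_strain,
                               elasticity = enface_elast),
                 labels = labels, masks = masks, config = config),
            class = "idc_report")
}

# horizontal step-response lines through the label image's boundaries:
# scans the row through the dense centroid for adipose|stroma and
# stroma|idc transitions and centres a sampling line on each
boundary_profiles <- function(enface_strain, enface_elast, labels,
                              pitch_um, halfwidth_um) {
  cen <- round(mean(which(labels > 0L, arr.ind = TRUE)[, 2]))
  cen <- min(max(cen, 1L), ncol(labels))
  row_lab <- labels[, cen]
  profiles <- list()
  add_line <- function(ix, tag) {
    x_um <- (ix - 1) * pitch_um[1]
    p0 <- c(max(x_um - halfwidth_um, 0), (cen - 1) * pitch_um[2])
    p1 <- c(min(x_um + halfwidth_um, (nrow(labels) - 1) * pitch_um[1]),
            (cen - 1) * pitch_um[2])
    n <- max(5L, round((p1[1] - p0[1]) / pitch_um[1]) + 1L)
    profiles[[paste0(tag, "_strain")]] <<-
      extract_profile(abs(enface_strain), p0, p1, n, pitch_um)
    profiles[[paste0(tag, "_elasticity")]] <<-
      extract_profile(enface_elast, p0, p1, n, pitch_um)
  }
  trans <- which(diff(row_lab) != 0L)
  # first adipose->stroma and first stroma->idc transition along the row
  as_ix <- trans[row_lab[trans] == 0L & row_lab[trans + 1L] == 1L][1]
  si_ix <- trans[row_lab[trans] == 1L & row_lab[trans + 1L] == 2L][1]
  if (!is.na(as_ix)) add_line(as_ix, "stroma_adipose")
  if (!is.na(si_ix)) add_line(si_ix, "idc_stroma")
  profiles
}

#' Duct-phantom experiment: hollow versus fluid-filled response
#'
#' Builds a compact duct phantom (straight main duct with one branch, 1 mm
#' and 0.8 mm diameters), simulates and reconstructs, and reports duct
#' interior masking/strain plus a cross-duct step-response analysis.
#'
#' @param config An [experiment_config()].
#' @param fill `"hollow"` or `"fluid"`.
#' @param pitch_um Voxel pitch (default c(50, 50, 25)).
#' @param spec Optional [duct_network_spec()]; a compact two-segment network
#'   is built when `NULL`.
#' @return List (class `duct_report`) with `duct_stats`, `resolution`,
#'   `enface`, `config`.
#' @export
run_duct_experiment <- function(config, fill = c("hollow", "fluid"),
                                pitch_um = c(50, 50, 25), spec = NULL) {
  fill <- match.arg(fill)
  if (is.null(spec)) spec <- compact_duct_network(fill)
  ph <- make_duct_phantom(spec, pitch_um = pitch_um, margin_mm = 1)
  # reconstruct without the SNR gate so that duct-interior voxels keep their
  # (erroneous, noise-driven) values for the step-response profiles — the
  # masking statistics below re-apply the gate, mirroring the display
  # convention of masking hollow-duct interiors after reconstruction
  cfg_ungated <- config
  cfg_ungated$snr_gate_db <- -100
  res <- simulate_and_reconstruct(ph, cfg_ungated)
  php <- res$phantom
  d <- dim(php$labels)
  duct3 <- php$labels == DUCT_LABELS[["duct"]]
  bulk3 <- php$labels == DUCT_LABELS[["bulk"]]
  # restrict to the sample part (below the layer)
  sample_z <- (php$interface_z + 1L):d[3]
  gate <- snr_db(res$unloaded) >= config$snr_gate_db
  strain <- res$strain$strain
  strain[!gate] <- NA_real_
  elast <- res$elast$elasticity

  duct_strain <- strain[, , sample_z][duct3[, , sample_z]]
  bulk_strain <- strain[, , sample_z][bulk3[, , sample_z]]
  duct_stats <- data.frame(
    fill = fill,
    duct_voxels = sum(duct3),
    duct_valid_frac = mean(is.finite(duct_strain)),
    duct_strain_median = stats::median(duct_strain, na.rm = TRUE),
    bulk_strain_median = stats::median(bulk_strain, na.rm = TRUE),
    bulk_elast_median_kpa = stats::median(
      elast[, , sample_z][bulk3[, , sample_z] & gate[, , sample_z]],
      na.rm = TRUE))

  # en-face at the duct mid-depth (ungated maps, as displayed pre-masking)
  zc <- round(mean(which(duct3, arr.ind = TRUE)[, 3]))
  at_z <- max(php$interface_z + 1L,
              zc - round(config$enface_depth_um / pitch_um[3]) %/% 2L)
  enface_strain <- postprocess_enface(res$strain$strain,
                                      median_px = config$median_px,
                                      enface_depth_um = config$enface_depth_um,
                                      at_z = at_z, pitch_um = pitch_um)
  enface_elast <- postprocess_enface(elast, median_px = config$median_px,
                                     enface_depth_um = config$enface_depth_um,
                                     at_z = at_z, pitch_um = pitch_um)

  # boundary step response perpendicular to the (x-aligned) main duct, taken
  # upstream of the branch point; the line runs from the bulk to the duct
  # centerline so it crosses one boundary
  duct_xy <- which(apply(duct3, c(1, 2), any), arr.ind = TRUE)
  xc <- round(stats::quantile(duct_xy[, 1], 0.15, names = FALSE))
  yc <- round(mean(duct_xy[duct_xy[, 1] == xc, 2]))
  half_um <- 1500
  p0 <- c((xc - 1) * pitch_um[1],
          max((yc - 1) * pitch_um[2] - half_um, 0))
  p1 <- c((xc - 1) * pitch_um[1], (yc - 1) * pitch_um[2])
  n <- max(5L, round((p1[2] - p0[2]) / pitch_um[2]) + 1L)
  profiles <- list(
    cross_duct_strain = extract_profile(abs(enface_strain), p0, p1, n,
                                        pitch_um),
    cross_duct_elasticity = extract_profile(enface_elast, p0, p1, n,
                                            pitch_um))
  structure(list(duct_stats = duct_stats,
                 resolution = resolution_report(profiles),
                 enface = list(strain = enface_strain,
                               elasticity = enface_elast),
                 phantom = php, config = config),
            class = "duct_report")
}

#' Compact duct network for desk-scale experiments
#'
#' A straight 10 mm main duct (diameter 1 mm) along x with a 4 mm branch
#' (diameter 0.8 mm) leaving at 45 degrees from its midpoint.
#'
#' @param fill `"hollow"` or `"fluid"`.
#' @return A [duct_network_spec()].
#' @export
compact_duct_network <- function(fill = c("hollow", "fluid")) {
  fill <- match.arg(fill)
  main <- cbind(x = seq(0, 10, by = 0.5), y = 0, z = 0)
  s <- seq(0, 4, by = 0.5)
  branch <- cbind(x = 5 + s * cos(pi / 4), y = s * sin(pi / 4), z = 0)
  duct_network_spec(
    list(list(points = main, diameter_mm = 1, name = "main"),
         list(points = branch, diameter_mm = 0.8, name = "branch")),
    fill = fill)
}

#' Write an experiment report to CSV files
#'
#' @param report An `idc_report` or `duct_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report_csv <- function(report, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in intersect(c("region_stats", "duct_stats", "resolution"),
                       names(report))) {
    if (is.null(report[[nm]])) next
    p <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    utils::write.csv(report[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
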