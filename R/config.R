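# YAML run configuration with strict key validation, and seeded fixture
# generation for the test suite. Units are embedded in key names
# (*_um, *_mm, *_kpa, *_db) to prevent silent unit errors.

run_config_schema <- c("seed", "prestrain", "actuation_strain",
                       "lambda0_nm", "refr_index", "noise_floor",
                       "pitch_um", "layer_thickness_um", "layer_kpa",
                       "fit_range_um", "snr_gate_db", "strain_floor",
                       "median_px", "enface_depth_um", "crop_px",
                       "coupling_fwhm_um", "noiseless",
                       "shape", "heights_um", "fill")

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; recognized keys are merged over the defaults
#' of [experiment_config()]. The returned object carries the extra geometry
#' keys (`shape`, `heights_um`, `fill`, `crop_px`) as attributes.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_schema)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$seed)) stop("config must set a seed")
  pitch <- if (!is.null(raw$pitch_um)) as.numeric(unlist(raw$pitch_um))
  else c(15, 15, 3.5)
  meta <- acquisition_meta(
    lambda0_nm = raw$lambda0_nm %||% 1300,
    refr_index = raw$refr_index %||% 1.4,
    noise_floor = raw$noise_floor %||% 1,
    pitch_um = pitch)
  layer <- compliant_layer(
    thickness_um = raw$layer_thickness_um %||% 500,
    secant_modulus_kpa = raw$layer_kpa %||% 16)
  cfg <- experiment_config(
    seed = raw$seed,
    prestrain = raw$prestrain %||% 0.05,
    actuation_strain = raw$actuation_strain %||% 0.001,
    meta = meta, layer = layer,
    fit_range_um = raw$fit_range_um %||% 100,
    snr_gate_db = raw$snr_gate_db %||% 5,
    strain_floor = raw$strain_floor %||% 1e-5,
    median_px = raw$median_px %||% 3,
    enface_depth_um = raw$enface_depth_um %||% 100,
    coupling_fwhm_um = raw$coupling_fwhm_um %||% 0,
    noiseless = raw$noiseless %||% FALSE)
  attr(cfg, "shape") <- if (!is.null(raw$shape))
    as.integer(unlist(raw$shape))
  attr(cfg, "heights_um") <- if (!is.null(raw$heights_um))
    unlist(raw$heights_um)
  attr(cfg, "fill") <- raw$fill
  attr(cfg, "crop_px") <- raw$crop_px
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the deterministic fixture set used by the test suite
#'
#' Writes, under `dir`: small nested dense/IDC masks (PNG), the toy
#' segmentation SNR image (CSV: a 12,000-px blob containing a 100-px hole, a
#' separate 500-px blob, 10 dB background), a phase-wrap displacement
#' fixture (CSV A-line), and noiseless/noisy erf edge profiles (CSV).
#' Identical seeds give identical files.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
make_fixtures <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- make_synthetic_masks(c(64, 64), c(40, 40), seed)
  write_mask_png(masks$dense, file.path(dir, "dense_mask.png"))
  write_mask_png(masks$idc, file.path(dir, "idc_mask.png"))
  img <- toy_segmentation_image()
  utils::write.table(img, file.path(dir, "toy_segmentation_db.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  # depth ramp whose phase crosses +/- pi several times
  z <- seq_len(200)
  u_um <- 0.004 * z                       # 4 nm per voxel ramp
  utils::write.table(data.frame(z = z, u_um = u_um),
                     file.path(dir, "wrap_ramp.csv"),
                     sep = ",", row.names = FALSE)
  prof <- synthetic_erf_profile(128.25)
  noisy <- synthetic_erf_profile(128.25, noise_sd = 0.05, seed = seed)
  utils::write.table(
    data.frame(x_um = prof$positions_um, clean = prof$values,
               noisy = noisy$values),
    file.path(dir, "erf_profiles.csv"), sep = ",", row.names = FALSE)
  invisible(dir)
}

#' Toy segmentation SNR image
#'
#' 200 x 150 image at 10 dB background with a 120 x 100 pixel (12,000 px)
#' 30 dB blob containing a 10 x 10 hole, and a separate 25 x 20 (500 px)
#' 30 dB blob.
#'
#' @return Numeric matrix of dB values.
#' @export
toy_segmentation_image <- function() {
  img <- matrix(10, 200, 150)
  img[11:130, 11:110] <- 30               # 12,000 px blob
  img[60:69, 50:59] <- 10                 # 100 px hole inside it
  img[150:174, 120:139] <- 30             # 500 px blob
  img
}
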