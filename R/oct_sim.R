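# Synthetic phase-sensitive OCT: complex tomograms with region-dependent
# speckle brightness and displacement encoded in the interferometric phase.

#' Acquisition metadata
#'
#' @param lambda0_nm Central wavelength in nm (default 1300).
#' @param refr_index Group refractive index of the medium (default 1.4,
#'   silicone/tissue).
#' @param noise_floor Noise-floor mean intensity in linear units (> 0).
#' @param pitch_um Voxel pitch (dx, dy, dz) in micrometres.
#' @return Object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(lambda0_nm = 1300, refr_index = 1.4,
                             noise_floor = 1, pitch_um = c(15, 15, 3.5)) {
  stopifnot(lambda0_nm > 0, refr_index >= 1, noise_floor > 0,
            length(pitch_um) == 3L, all(pitch_um > 0))
  structure(list(lambda0_nm = lambda0_nm, refr_index = refr_index,
                 noise_floor = noise_floor, pitch_um = as.numeric(pitch_um)),
            class = "acquisition_meta")
}

#' Complex tomogram container
#' @param field 3D complex array.
#' @param meta An [acquisition_meta()].
#' @return Object of class `complex_tomogram`.
#' @export
complex_tomogram <- function(field, meta) {
  stopifnot(is.array(field), length(dim(field)) == 3L,
            inherits(meta, "acquisition_meta"))
  structure(list(field = field, meta = meta), class = "complex_tomogram")
}

#' Simulate a speckled complex tomogram of a phantom
#'
#' Each voxel is drawn as a circularly-symmetric complex Gaussian whose mean
#' intensity is `noise_floor * 10^(backscatter_dB/10)` for its region, plus
#' additive complex Gaussian noise at the noise floor (the two independent
#' Gaussian components are drawn as a single complex Gaussian with summed
#' variance, which is the same distribution). Void voxels are noise-only.
#' Speckle is voxel-independent (no lateral correlation). Deterministic under
#' a fixed seed.
#'
#' @param phantom A `phantom_model`.
#' @param meta An [acquisition_meta()]; pitch must agree with the phantom.
#' @param seed Integer seed.
#' @param signal_only If `TRUE`, omit the additive noise term (used to build
#'   correlated loaded/unloaded pairs; see [oct_pair()]).
#' @return A [complex_tomogram()].
#' @export
simulate_speckle <- function(phantom, meta, seed, signal_only = FALSE) {
  if (!isTRUE(all.equal(meta$pitch_um, phantom$pitch_um)))
    stop("phantom and acquisition pitches disagree")
  bs <- backscatter_grid(phantom)
  mean_int <- meta$noise_floor * 10^(bs / 10)
  mean_int[!is.finite(mean_int)] <- 0        # void: signal-free
  total_var <- mean_int + if (signal_only) 0 else meta$noise_floor
  d <- dim(bs)
  n <- prod(d)
  set.seed(as.integer(seed))
  re <- stats::rnorm(n, sd = sqrt(total_var / 2))
  im <- stats::rnorm(n, sd = sqrt(total_var / 2))
  field <- array(complex(real = re, imaginary = im), dim = d)
  complex_tomogram(field, meta)
}

#' Apply an axial displacement field to a tomogram's phase
#'
#' Double-pass, common-path phase encoding:
#' `loaded = unloaded * exp(i * dphi)` with `dphi = 4 * pi * n * u / lambda0`.
#' Amplitude is unchanged (small-displacement regime). Voxels whose
#' displacement exceeds `decorrelation_fraction * dz` trigger a warning (in a
#' real system such motion decorrelates the speckle).
#'
#' @param tom A [complex_tomogram()].
#' @param disp A [displacement_field()] in micrometres on the same grid.
#' @param decorrelation_fraction Warning threshold as a fraction of dz.
#' @return The loaded [complex_tomogram()].
#' @export
apply_displacement <- function(tom, disp, decorrelation_fraction = 0.5) {
  stopifnot(inherits(tom, "complex_tomogram"),
            inherits(disp, "displacement_field"))
  if (!identical(dim(tom$field), dim(disp$u)))
    stop("tomogram and displacement grids differ")
  u <- ifelse(disp$valid, disp$u, 0)
  umax <- max(abs(u))
  if (umax > decorrelation_fraction * tom$meta$pitch_um[3])
    warning(sprintf(
      "max |u| = %.3g um exceeds %g x dz: speckle decorrelation regime",
      umax, decorrelation_fraction))
  dphi <- phase_per_um(tom$meta) * u
  complex_tomogram(tom$field * exp(1i * dphi), tom$meta)
}

# radians of double-pass phase per micrometre of displacement
phase_per_um <- function(meta) {
  4 * pi * meta$refr_index / (meta$lambda0_nm / 1000)
}

#' Simulate a correlated unloaded/loaded tomogram pair
#'
#' The sample's scatterer configuration is unchanged between the two
#' acquisitions, so the speckle (signal) realization is shared and the
#' displacement appears as a pure phase shift; the detection noise is drawn
#' independently for each acquisition.
#'
#' @param phantom A `phantom_model`.
#' @param meta An [acquisition_meta()].
#' @param disp A [displacement_field()] (micrometres).
#' @param seed Integer seed.
#' @param noiseless If `TRUE`, omit additive noise entirely (both tomograms
#'   share the exact same realization up to the phase term).
#' @return List with `unloaded` and `loaded` [complex_tomogram()]s.
#' @export
oct_pair <- function(phantom, meta, disp, seed, noiseless = FALSE) {
  signal <- simulate_speckle(phantom, meta, seed, signal_only = TRUE)
  u <- ifelse(disp$valid, disp$u, 0)
  dphi <- phase_per_um(meta) * u
  if (noiseless) {
    unloaded <- signal
    loaded <- complex_tomogram(signal$field * exp(1i * dphi), meta)
    return(list(unloaded = unloaded, loaded = loaded))
  }
  n <- prod(dim(signal$field))
  sd_n <- sqrt(meta$noise_floor / 2)
  set.seed(as.integer(seed) + 1L)
  noise1 <- complex(real = stats::rnorm(n, sd = sd_n),
                    imaginary = stats::rnorm(n, sd = sd_n))
  noise2 <- complex(real = stats::rnorm(n, sd = sd_n),
                    imaginary = stats::rnorm(n, sd = sd_n))
  unloaded <- array(signal$field + noise1, dim = dim(signal$field))
  loaded <- array(signal$field * exp(1i * dphi) + noise2,
                  dim = dim(signal$field))
  list(unloaded = complex_tomogram(unloaded, meta),
       loaded = complex_tomogram(loaded, meta))
}

#' Per-voxel OCT signal-to-noise ratio in dB
#'
#' @param tom A [complex_tomogram()].
#' @return 3D numeric array: `10 * log10(|field|^2 / noise_floor)`.
#' @export
snr_db <- function(tom) {
  stopifnot(inherits(tom, "complex_tomogram"))
  10 * log10((Mod(tom$field)^2) / tom$meta$noise_floor)
}
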