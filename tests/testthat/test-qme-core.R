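test_that("phase-difference displacement inverts the encoding below the
           wrap limit", {
  meta <- acquisition_meta(pitch_um = c(20, 20, 10))
  ph <- make_slab_phantom(c(8, 8, 30), material_spec("s", 48, 30),
                          c(20, 20, 10))
  set.seed(9)
  u_true <- array(runif(8 * 8 * 30, -0.1, 0.1), dim = c(8, 8, 30))
  pair <- oct_pair(ph, meta, displacement_field(u_true), seed = 9,
                   noiseless = TRUE)
  pd <- phase_difference_displacement(pair$unloaded, pair$loaded,
                                      snr_gate_db = -50)
  rms_nm <- sqrt(mean((pd$disp$u - u_true)^2)) * 1000
  expect_lt(rms_nm, 1e-6)   # machine-precision round trip, well under 1 nm
  # identical inputs give zero displacement
  pd0 <- phase_difference_displacement(pair$unloaded, pair$unloaded)
  expect_true(all(pd0$disp$u == 0))
})

test_that("depth unwrapping keeps ramps continuous across the +/- pi wraps", {
  meta <- acquisition_meta(pitch_um = c(20, 20, 10))
  ph <- make_slab_phantom(c(4, 4, 200), material_spec("s", 48, 30),
                          c(20, 20, 10))
  # 100 nm/voxel ramp: total phase ~ 270 rad, crossing +/- pi repeatedly
  u_ramp <- array(rep(0.1 * (200:1), each = 16), dim = c(4, 4, 200))
  pair <- oct_pair(ph, meta, displacement_field(u_ramp), seed = 1,
                   noiseless = TRUE)
  pd <- phase_difference_displacement(pair$unloaded, pair$loaded,
                                      snr_gate_db = -50)
  du <- apply(pd$disp$u, c(1, 2), diff)
  wrap_limit <- 1300 / (8 * 1.4) / 1000       # lambda0/(8n) in um
  expect_lt(max(abs(du)), wrap_limit)
  # slope (strain) is recovered exactly despite the per-line phase offset
  expect_equal(as.vector(du), rep(-0.1, length(du)), tolerance = 1e-9)
})

test_that("wls_strain is exact on lines and matches the normal-equation
           oracle", {
  pitch <- c(20, 20, 10)
  d <- c(3, 3, 40)
  z_abs <- (seq_len(d[3])) * pitch[3]
  u_lin <- array(rep(5 - 0.002 * z_abs, each = 9), dim = d)
  disp <- displacement_field(u_lin)
  s <- wls_strain(disp, NULL, fit_range_um = 100, pitch_um = pitch)
  expect_equal(s$strain, array(-0.002, dim = d), tolerance = 1e-12)
  # constant displacement gives zero strain
  s0 <- wls_strain(displacement_field(array(3, dim = d)), NULL, 100, pitch)
  expect_equal(s0$strain, array(0, dim = d), tolerance = 1e-12)

  # random noisy ramp with heteroscedastic weights vs direct solve
  set.seed(21)
  u_noisy <- u_lin + array(rnorm(prod(d), sd = 0.05), dim = d)
  w <- array(rexp(prod(d)) + 0.1, dim = d)
  sw <- wls_strain(displacement_field(u_noisy), w, 100, pitch)
  win <- round(100 / pitch[3])           # 10 samples, centred window
  half_lo <- (win - 1) %/% 2
  zc <- z_abs - mean(z_abs)              # same centring as the implementation
  for (k in c(6, 17, 33)) for (i in 1:3) for (j in 1:3) {
    idx <- (k - half_lo):(k - half_lo + win - 1)
    oracle <- wls_slope_oracle(zc[idx], u_noisy[i, j, idx], w[i, j, idx])
    expect_equal(sw$strain[i, j, k], oracle, tolerance = 1e-10)
  }
})

test_that("wls_strain handles invalid samples, short windows and zero
           weights", {
  pitch <- c(20, 20, 5)
  expect_error(wls_strain(displacement_field(array(0, c(2, 2, 10))),
                          NULL, 10, pitch), "at least 3")
  d <- c(2, 2, 30)
  u <- array(1, dim = d)
  valid <- array(TRUE, dim = d)
  valid[1, 1, ] <- FALSE                  # fully invalid line
  s <- wls_strain(displacement_field(u, valid), NULL, 100, pitch)
  expect_true(all(is.na(s$strain[1, 1, ])))
  expect_true(all(is.finite(s$strain[2, 2, ])))
  # all-zero weights in the window invalidate the voxel
  w <- array(1, dim = d); w[2, 1, ] <- 0
  sw <- wls_strain(displacement_field(u), w, 100, pitch)
  expect_true(all(is.na(sw$strain[2, 1, ])))
})

test_that("layer stress follows the stress-strain curve", {
  d <- c(2, 2, 120)
  strain <- strain_field(array(-0.10, dim = d))
  lay <- compliant_layer(500, secant_modulus_kpa = 16)
  sm <- layer_stress(strain, lay, interface_z = 100L,
                     pitch_um = c(20, 20, 5))
  expect_equal(sm$stress[1, 1], 1.6, tolerance = 1e-12)
  # zero strain -> zero stress
  sm0 <- layer_stress(strain_field(array(0, dim = d)), lay, 100L,
                      c(20, 20, 5))
  expect_equal(sm0$stress[2, 2], 0)
  # piecewise-linear curve evaluated off-knot by interpolation
  curve <- approxfun(c(0, 0.05, 0.2), c(0, 1, 7))
  layp <- compliant_layer(500, stress_strain = curve)
  strain2 <- strain_field(array(-0.10, dim = d))
  smp <- layer_stress(strain2, layp, 100L, c(20, 20, 5))
  expect_equal(smp$stress[1, 1], 1 + 0.05 / 0.15 * 6, tolerance = 1e-12)
  # no valid layer strain -> invalid position
  sv <- array(NA_real_, dim = d)
  smv <- layer_stress(strain_field(sv), lay, 100L, c(20, 20, 5))
  expect_false(any(smv$valid))
})

test_that("elasticity map divides stress by |strain| with a floor", {
  strain <- strain_field(array(-1.6 / 48, dim = c(2, 2, 5)))
  sm <- stress_map(matrix(1.6, 2, 2))
  el <- elasticity_map(sm, strain)
  expect_equal(el$elasticity, array(48, dim = c(2, 2, 5)),
               tolerance = 1e-12)
  tiny <- strain_field(array(-1e-6, dim = c(2, 2, 5)))
  el2 <- elasticity_map(sm, tiny)
  expect_true(all(is.na(el2$elasticity)))
})

test_that("postprocessing crops, median-filters and averages as specified", {
  vol <- array(rep(1:10, each = 800 * 800 / 10), dim = c(800, 800, 1))
  out <- postprocess_enface(vol, crop_px = c(700, 700), median_px = 1,
                            enface_depth_um = 100, at_z = 1L,
                            pitch_um = c(15, 15, 3.5))
  expect_identical(dim(out), c(700L, 700L))
  # 700 px at 15 um spans 10.5 mm
  expect_equal(700 * 15 / 1000, 10.5)
  expect_error(postprocess_enface(vol, crop_px = c(900, 900),
                                  pitch_um = c(15, 15, 3.5)),
               "crop larger")
  # single salt pixel removed by the 3x3 median
  plane <- matrix(5, 21, 21); plane[11, 11] <- 100
  filt <- median_filter2(plane, 3)
  expect_equal(filt, matrix(5, 21, 21))
  # median of a constant image is unchanged
  expect_equal(median_filter2(matrix(2, 9, 9), 3), matrix(2, 9, 9))
})

test_that("crop/filter/en-face operations are scale-equivariant", {
  set.seed(3)
  vol <- array(rexp(40 * 40 * 12), dim = c(40, 40, 12))
  vol[vol > 3] <- NA
  a <- postprocess_enface(vol, crop_px = c(30, 30), median_px = 3,
                          enface_depth_um = 50, at_z = 2L,
                          pitch_um = c(20, 20, 10))
  b <- postprocess_enface(vol * 7.5, crop_px = c(30, 30), median_px = 3,
                          enface_depth_um = 50, at_z = 2L,
                          pitch_um = c(20, 20, 10))
  expect_equal(b, a * 7.5, tolerance = 1e-12)
})

test_that("noiseless pipeline recovers the modulus grid within 1%", {
  mats <- list(`0` = material_spec("a", 18, 17),
               `1` = material_spec("b", 48, 30))
  labels <- array(0L, dim = c(24, 24, 120))
  labels[9:24, , ] <- 1L                  # lateral bi-material block
  ph <- phantom_model(labels, mats, c(20, 20, 10))
  cfg <- experiment_config(seed = 5, noiseless = TRUE)
  res <- simulate_and_reconstruct(ph, cfg)
  php <- res$phantom
  win_half <- 5L                          # half the 100 um / 10 um window
  zs <- (php$interface_z + win_half + 2L):(dim(php$labels)[3] - win_half - 1L)
  E_true <- modulus_grid(php)[, , zs]
  E_rec <- res$elast$elasticity[, , zs]
  rel <- abs(E_rec - E_true) / E_true
  expect_lt(max(rel, na.rm = TRUE), 0.01)
  # region ordering matches ground truth everywhere
  expect_gt(min(E_rec[9:24, , ], na.rm = TRUE),
            max(E_rec[1:8, , ], na.rm = TRUE) - 1e-9)
})
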