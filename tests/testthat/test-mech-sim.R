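test_that("homogeneous column stress obeys sigma = E * prestrain", {
  ph <- make_slab_phantom(c(3, 3, 40), material_spec("b", 58, 25),
                          c(25, 25, 25))
  sm <- solve_prestrain_stress(ph, 0.05)
  expect_equal(sm$stress[2, 2], 2.9, tolerance = 1e-12)
  sm0 <- solve_prestrain_stress(ph, 0)
  expect_true(all(sm0$stress == 0))
})

test_that("series-spring bilayer matches the hand calculation", {
  ph <- small_bilayer_phantom()        # 500 um @ 16 kPa over 1000 um @ 48
  # sigma = 1.6 kPa -> strains 0.10 and 0.0333, mean compression 0.0667
  sm <- stress_map(matrix(1.6, 4, 4))
  mech <- series_spring_deform(ph, sm)
  expect_equal(mech$strain$strain[1, 1, 50], -0.10, tolerance = 1e-12)
  expect_equal(mech$strain$strain[1, 1, 200], -1.6 / 48, tolerance = 1e-12)
  # top-surface displacement magnitude 0.10*500 + 0.0333*1000 = 83.33 um
  expect_equal(abs(mech$disp$u[1, 1, 1]), 0.10 * 500 + 1.6 / 48 * 1000,
               tolerance = 1e-9)
  expect_equal(mech$disp$u[1, 1, 300], -mech$strain$strain[1, 1, 300] * 5,
               tolerance = 1e-12)       # u -> 0 at the fixed plate
  # solve_prestrain_stress inverts the forward deformation
  mean_comp <- (0.10 * 500 + 1.6 / 48 * 1000) / 1500
  sm2 <- solve_prestrain_stress(ph, mean_comp)
  expect_equal(sm2$stress[1, 1], 1.6, tolerance = 1e-10)
  # equal-thickness 16/48 bilayer at sigma = 1.6: mean compression 0.0667
  labels <- array(0L, dim = c(1, 1, 200)); labels[, , 101:200] <- 1L
  ph_eq <- phantom_model(labels, list(`0` = material_spec("soft", 16),
                                      `1` = material_spec("stiff", 48)),
                         c(15, 15, 5))
  sm3 <- solve_prestrain_stress(ph_eq, (0.10 + 1.6 / 48) / 2)
  expect_equal(sm3$stress[1, 1], 1.6, tolerance = 1e-10)
})

test_that("column compression is conserved and softer regions deform more", {
  set.seed(7)
  mats <- list(`0` = material_spec("a", 18, 17),
               `1` = material_spec("b", 48, 30),
               `2` = material_spec("c", 230, 23))
  labels <- array(sample(0:2, 5 * 5 * 60, replace = TRUE), dim = c(5, 5, 60))
  ph <- phantom_model(labels, mats, c(20, 20, 10))
  prestrain <- 0.05
  sm <- solve_prestrain_stress(ph, prestrain)
  mech <- series_spring_deform(ph, sm)
  E <- modulus_grid(ph)
  for (i in 1:5) for (j in 1:5) {
    s <- mech$strain$strain[i, j, ]
    expect_equal(sum(s) * 10, -prestrain * 600, tolerance = 1e-9)
    # |strain| ordering opposite to E ordering within the column
    expect_equal(order(abs(s)), order(1 / E[i, j, ]))
  }
  expect_true(all(mech$strain$strain < 0))
})

test_that("nonlinear layer curves are solved to the bisection tolerance", {
  soft <- material_spec("soft", 16, 25)
  stiff <- material_spec("stiff", 48, 30)
  labels <- array(0L, dim = c(2, 2, 300))
  labels[, , 101:300] <- 1L
  ph <- phantom_model(labels, list(`0` = soft, `1` = stiff), c(15, 15, 5))
  curve <- function(e) 16 * e + 40 * e^2          # stiffening layer
  ph$layer <- compliant_layer(500, stress_strain = curve,
                              secant_modulus_kpa = 16)
  ph$layer_id <- 0L
  sm <- solve_prestrain_stress(ph, 0.05)
  sigma <- sm$stress[1, 1]
  # residual of the column equation at the solved stress
  e_layer <- uniroot(function(e) curve(e) - sigma, c(0, 0.2),
                     tol = 1e-14)$root
  compression <- e_layer * 500 + sigma / 48 * 1000
  expect_equal(compression, 0.05 * 1500, tolerance = 1e-6)
})

test_that("void columns are excluded and fully-void columns invalidated", {
  mats <- list(`0` = material_spec("b", 58, 25), `1` = duct_void_material())
  labels <- array(0L, dim = c(2, 1, 20))
  labels[1, 1, 6:10] <- 1L               # partial void column
  labels[2, 1, ] <- 1L                   # fully void column
  ph <- phantom_model(labels, mats, c(25, 25, 25))
  sm <- solve_prestrain_stress(ph, 0.05)
  expect_false(sm$valid[2, 1])
  # partial void column: solid part still strains at sigma/E = prestrain
  expect_equal(sm$stress[1, 1], 2.9, tolerance = 1e-12)
  mech <- series_spring_deform(ph, sm)
  expect_true(all(is.na(mech$strain$strain[1, 1, 6:10])))
  expect_true(all(is.na(mech$strain$strain[2, 1, ])))
})

test_that("lateral coupling blur is an identity at zero and preserves
           constants", {
  s <- array(rnorm(10 * 10 * 3, -0.01, 0.001), dim = c(10, 10, 3))
  f <- strain_field(s)
  expect_identical(lateral_coupling_blur(f, 0, c(20, 20, 10))$strain, s)
  const <- strain_field(array(-0.02, dim = c(12, 12, 2)))
  b <- lateral_coupling_blur(const, 150, c(20, 20, 10))
  expect_equal(b$strain, const$strain, tolerance = 1e-12)
})

test_that("a blurred step has an erf profile with the kernel's FWHM", {
  kernel_fwhm <- 400
  pitch <- c(20, 20, 10)
  s <- array(-0.005, dim = c(200, 40, 1))
  s[101:200, , ] <- -0.02
  b <- lateral_coupling_blur(strain_field(s), kernel_fwhm, pitch)
  prof <- extract_profile(abs(b$strain[, , 1]),
                          p0 = c(99.5 * 20 - 1200, 20 * 20),
                          p1 = c(99.5 * 20 + 1200, 20 * 20),
                          n_samples = 121, pitch_um = pitch[1:2])
  fit <- fit_erf(prof)
  expect_equal(fit$fwhm_um, kernel_fwhm, tolerance = 0.02)
})
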