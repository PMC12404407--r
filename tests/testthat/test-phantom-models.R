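test_that("material invariants are enforced", {
  expect_error(material_spec("x", -5), "positive")
  expect_error(material_spec("x", 10, Inf), "finite")
  expect_error(material_spec("x", 10, 0, is_fluid = TRUE, is_void = TRUE),
               "void and fluid")
  m <- idc_phantom_materials()
  expect_equal(m$adipose$youngs_modulus_kpa, 18)
  expect_equal(m$idc$youngs_modulus_kpa, 230)
  expect_equal(m$stroma$youngs_modulus_kpa, 48)
  expect_equal(m$stroma$backscatter_db, 30)
  expect_equal(m$idc$backscatter_db, 23)
  expect_equal(m$adipose$backscatter_db, 17)
  expect_equal(duct_bulk_material()$youngs_modulus_kpa, 58)
})

test_that("IDC phantom labels follow the masks voxel for voxel", {
  masks <- tiny_idc_masks()
  heights <- c(cover = 200, structure = 1000, base = 1000)
  ph <- make_idc_phantom(masks$dense, masks$idc, heights,
                         pitch_um = c(20, 20, 10))
  n_struct <- 100L
  # brute-force voxel count oracle over the structure section
  struct <- ph$labels[, , ph$structure_z]
  n_stroma <- sum(masks$dense & !masks$idc) * n_struct
  n_idc <- sum(masks$idc) * n_struct
  expect_identical(sum(struct == IDC_LABELS[["stroma"]]), n_stroma)
  expect_identical(sum(struct == IDC_LABELS[["idc"]]), n_idc)
  # mask-faithful: projecting any structure plane reproduces the masks
  mid <- ph$structure_z[50]
  expect_identical(ph$labels[, , mid] >= IDC_LABELS[["stroma"]], masks$dense)
  expect_identical(ph$labels[, , mid] == IDC_LABELS[["idc"]], masks$idc)
  # cover defaults to stroma, base to adipose
  expect_true(all(ph$labels[, , 1] == IDC_LABELS[["stroma"]]))
  expect_true(all(ph$labels[, , dim(ph$labels)[3]] ==
                    IDC_LABELS[["adipose"]]))
})

test_that("empty masks give an all-adipose phantom; misnested masks error", {
  empty <- matrix(FALSE, 20, 20)
  ph <- make_idc_phantom(empty, empty, pitch_um = c(20, 20, 10))
  expect_true(all(ph$labels[, , ph$structure_z] == IDC_LABELS[["adipose"]]))
  bad_idc <- matrix(FALSE, 20, 20); bad_idc[1:3, 1:3] <- TRUE
  dense <- matrix(FALSE, 20, 20); dense[10:15, 10:15] <- TRUE
  expect_error(make_idc_phantom(dense, bad_idc, pitch_um = c(20, 20, 10)),
               "9 pixel")
})

test_that("every voxel label must carry a material", {
  labels <- array(c(0L, 3L), dim = c(2, 1, 1))
  expect_error(phantom_model(labels, list(`0` = material_spec("a", 1)),
                             c(10, 10, 10)),
               "without a material")
})

test_that("attach_layer prepends the right number of planes and guards", {
  ph <- make_slab_phantom(c(4, 4, 50), material_spec("s", 48, 30),
                         c(15, 15, 5))
  lay <- compliant_layer(500, secant_modulus_kpa = 16)
  ph2 <- attach_layer(ph, lay)
  expect_identical(dim(ph2$labels)[3], 150L)
  expect_identical(ph2$interface_z, 100L)
  expect_equal(lay$stress_strain(0.10), 1.6)   # sigma = E * eps by hand
  expect_error(attach_layer(ph2, lay), "already has")
  # off-multiple thickness rounds to the nearest whole plane
  ph3 <- attach_layer(ph, compliant_layer(493))
  expect_identical(ph3$interface_z, 99L)
  expect_error(attach_layer(ph, compliant_layer(1)), "thinner")
})

test_that("compliant layer curve invariants hold", {
  expect_error(compliant_layer(0), "positive")
  expect_error(compliant_layer(500, stress_strain = function(e) e - 0.01),
               "must be 0")
  expect_error(compliant_layer(500, stress_strain = function(e) -e + 2 * e^2),
               "increasing")
})

test_that("centerline distance grid matches a brute-force oracle", {
  set.seed(42)
  poly <- matrix(runif(9, 0.2, 1.8), 3, 3)
  shape <- c(8, 7, 6)
  pitch <- c(250, 250, 300)
  dist <- rasterize_centerline_distance(poly, shape, pitch)
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3])) {
        p <- c((i - 1) * 0.25, (j - 1) * 0.25, (k - 1) * 0.3)
        expect_equal(dist[i, j, k], brute_polyline_dist(p, poly),
                     tolerance = 1e-9)
      }
  # on-axis and perpendicular sanity
  seg <- rbind(c(0, 0.5, 0.5), c(2, 0.5, 0.5))
  d2 <- rasterize_centerline_distance(seg, c(5, 3, 3), c(500, 500, 500))
  expect_equal(d2[3, 2, 2], 0)
  expect_equal(d2[3, 3, 2], 0.5)
})

test_that("duct voxel volume converges to the analytic cylinder volume", {
  tube <- duct_network_spec(
    list(list(points = cbind(seq(0, 10, 1), 0, 0), diameter_mm = 0.8)),
    fill = "hollow")
  truth <- pi * 0.4^2 * 10
  errs <- vapply(c(50, 25), function(p) {
    ph <- make_duct_phantom(tube, pitch_um = rep(p, 3), margin_mm = 0.5)
    vol <- sum(ph$labels == DUCT_LABELS[["duct"]]) * prod(ph$pitch_um / 1e3)
    abs(vol - truth) / truth
  }, numeric(1))
  expect_lt(errs[2], 0.03)
  expect_lt(errs[2], errs[1])    # strictly decreasing with pitch
})

test_that("empty duct network yields no duct voxels; thin ducts refused", {
  ph <- make_duct_phantom(duct_network_spec(list(), fill = "hollow"),
                          shape = c(10, 10, 10), pitch_um = c(50, 50, 50))
  expect_identical(sum(ph$labels == DUCT_LABELS[["duct"]]), 0L)
  thin <- duct_network_spec(
    list(list(points = cbind(c(0, 1), 0, 0), diameter_mm = 0.05)),
    fill = "hollow")
  expect_error(make_duct_phantom(thin, pitch_um = c(50, 50, 50)),
               "unresolvable")
})

test_that("default duct network has the designed branch geometry", {
  spec <- default_duct_network()
  expect_equal(spec$segments[[1]]$diameter_mm, 1.0)
  expect_equal(spec$segments[[2]]$diameter_mm, 0.8)
  # branch starts on the main centerline at 11 mm arc length
  main <- spec$segments[[1]]$points
  arc <- c(0, cumsum(sqrt(rowSums(diff(main)^2))))
  b0 <- spec$segments[[2]]$points[1, ]
  d_to_main <- brute_polyline_dist(b0, main)
  expect_lt(d_to_main, 1e-6)
  i_near <- which.min(sqrt(rowSums(sweep(main, 2, b0)^2)))
  expect_equal(arc[i_near], 11, tolerance = 0.26)  # one sampling step
  # fluid fill carries a fluid material, hollow a void
  expect_true(make_duct_phantom(default_duct_network("fluid"),
                                pitch_um = c(100, 100, 100),
                                margin_mm = 0.5
              )$materials[["1"]]$is_fluid)
})
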