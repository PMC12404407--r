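test_that("mask extrusion produces watertight prisms with countable
           volume", {
  # single pixel at 20 um pitch, 1 mm height: a 4e-4 mm^3 cuboid
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  mesh1 <- extrude_mask(m1, c(20, 20), height_mm = 1)
  expect_true(is_watertight(mesh1))
  expect_equal(mesh_volume(mesh1), 4e-4, tolerance = 1e-9)

  # random multi-pixel mask: divergence-theorem volume equals the count
  set.seed(17)
  m <- matrix(runif(30 * 25) < 0.35, 30, 25)
  m[1, 1] <- TRUE
  mesh <- extrude_mask(m, c(40, 30), height_mm = 0.7)
  expect_true(is_watertight(mesh))
  expect_equal(mesh_volume(mesh), sum(m) * 0.04 * 0.03 * 0.7,
               tolerance = 1e-9)
  expect_error(extrude_mask(matrix(FALSE, 4, 4), c(20, 20), 1), "empty")
})

test_that("a mask with a hole extrudes to a watertight genus-1 prism", {
  m <- matrix(FALSE, 12, 12)
  m[3:10, 3:10] <- TRUE
  m[6:7, 6:7] <- FALSE
  mesh <- extrude_mask(m, c(50, 50), height_mm = 1)
  expect_true(is_watertight(mesh))
  # Euler characteristic V - E + F = 0 for a torus-like surface
  dir_edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3],
                     mesh$faces[, c(3, 1)])
  keys <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                pmax(dir_edges[, 1], dir_edges[, 2]))
  chi <- nrow(mesh$vertices) - length(unique(keys)) + nrow(mesh$faces)
  expect_identical(chi, 0L)
  expect_equal(mesh_volume(mesh), (64 - 4) * 0.05 * 0.05,
               tolerance = 1e-9)
})

test_that("volume is additive over disjoint mask components", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE
  m[12:18, 12:15] <- TRUE
  whole <- mesh_volume(extrude_mask(m, c(20, 20), 1))
  m1 <- m; m1[12:18, 12:15] <- FALSE
  m2 <- m; m2[2:6, 2:6] <- FALSE
  expect_equal(whole, mesh_volume(extrude_mask(m1, c(20, 20), 1)) +
                 mesh_volume(extrude_mask(m2, c(20, 20), 1)),
               tolerance = 1e-12)
})

test_that("the cylindrical mold wall reproduces the design geometry", {
  centre <- extrude_mask(matrix(TRUE, 10, 10), c(100, 100), height_mm = 1)
  mold <- add_cylindrical_wall(centre, diameter_mm = 45, height_mm = 1.2,
                               base_thickness_mm = 1)
  expect_true(is_watertight(mold))
  # 0.2 mm clearance between structure (1 mm) and wall top (1.2 mm)
  expect_equal(max(mold$vertices[, 3]) - max(centre$vertices[, 3]), 0.2)
  # wall volume close to the analytic annulus at 1 degree resolution
  wall <- annulus_mesh(22.5, 24.5, 0, 1.2, n_theta = 360)
  expect_true(is_watertight(wall))
  expect_equal(mesh_volume(wall), pi * (24.5^2 - 22.5^2) * 1.2,
               tolerance = 0.03)
  expect_error(add_cylindrical_wall(centre, diameter_mm = 45,
                                    height_mm = 0), "positive")
  big <- extrude_mask(matrix(TRUE, 10, 10), c(5000, 5000), height_mm = 1)
  expect_error(add_cylindrical_wall(big), "exceeds")
})

test_that("swept duct tubes are watertight with the right surface area", {
  spec <- duct_network_spec(
    list(list(points = cbind(seq(0, 10, 0.5), 0, 0), diameter_mm = 1)),
    fill = "hollow")
  tube <- sweep_duct_tube(spec, wall_thickness_mm = 0.5,
                          disc_diameter_mm = NA, n_theta = 180)
  expect_true(is_watertight(tube))
  # outer lateral area ~ 2 pi r L: estimate from the outer-shell volume
  vol <- mesh_volume(tube)
  expect_equal(vol, pi * (1^2 - 0.5^2) * 10, tolerance = 0.03 * pi * 7.5)
  # with the disc shell: still watertight, ducts keep their diameters
  full <- sweep_duct_tube(default_duct_network(), n_theta = 60)
  expect_true(is_watertight(full))
  # sharp bends are refused
  kink <- duct_network_spec(
    list(list(points = rbind(c(0, 0, 0), c(1, 0, 0), c(0.1, 0.3, 0)),
              diameter_mm = 2, name = "kinked")),
    fill = "hollow")
  expect_error(sweep_duct_tube(kink, disc_diameter_mm = NA),
               "self-intersecting")
})

test_that("binary STL round trips preserve geometry", {
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE; m[3, 3] <- FALSE
  mesh <- extrude_mask(m, c(100, 100), height_mm = 1)
  path <- tempfile(fileext = ".stl")
  write_stl(mesh, path)
  back <- read_stl(path)
  expect_true(is_watertight(back))
  expect_identical(nrow(back$faces), nrow(mesh$faces))
  expect_equal(mesh_volume(back), mesh_volume(mesh), tolerance = 1e-5)
  # unit cube: 12 faces, 1 mm^3
  cube <- extrude_mask(matrix(TRUE, 1, 1), c(1000, 1000), height_mm = 1)
  p2 <- tempfile(fileext = ".stl")
  write_stl(cube, p2)
  cb <- read_stl(p2)
  expect_identical(nrow(cb$faces), 12L)
  expect_equal(mesh_volume(cb), 1, tolerance = 1e-9)
  # refuse a non-watertight mesh (single triangle) without force
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  expect_error(write_stl(tri, tempfile()), "watertight")
  expect_error(triangle_mesh(matrix(0, 0, 3), matrix(integer(0), 0, 3)),
               "empty")
})
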