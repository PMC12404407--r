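test_that("dense-tissue segmentation applies threshold, fill and area
           criterion", {
  img <- toy_segmentation_image()
  mask <- segment_dense_tissue(img, segmentation_params(23, 10000))
  lab <- label_components(mask)
  expect_identical(max(lab), 1L)
  expect_identical(sum(mask), 12000L)     # hole filled, small blob removed
  # the 100-px hole is inside the surviving component
  expect_true(all(mask[60:69, 50:59]))
  # uniform image below threshold -> empty mask
  expect_identical(sum(segment_dense_tissue(matrix(10, 50, 50),
                                            segmentation_params(23, 0))), 0L)
})

test_that("raising the threshold never grows the mask", {
  set.seed(13)
  img <- matrix(rnorm(80 * 80, 20, 8), 80, 80)
  img <- median_filter2(img, 5)
  prev <- matrix(TRUE, 80, 80)
  for (thr in c(15, 20, 25, 30)) {
    m <- segment_dense_tissue(img, segmentation_params(thr, 0,
                                                       fill_holes = FALSE))
    expect_true(all(prev | !m))           # m subset of prev
    prev <- m
  }
})

test_that("every surviving component has at least the minimum area", {
  set.seed(31)
  img <- matrix(sample(c(10, 30), 120 * 120, replace = TRUE,
                       prob = c(0.7, 0.3)), 120, 120)
  min_area <- 40L
  m <- segment_dense_tissue(img, segmentation_params(23, min_area))
  lab <- label_components(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    expect_true(all(areas[areas > 0] >= min_area))
  }
  # idempotence on its own output as a 0/1000 dB image
  m2 <- segment_dense_tissue(m * 1000, segmentation_params(23, min_area))
  expect_identical(m2, m)
})

test_that("4- and 8-connectivity differ exactly on diagonal touches", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(max(label_components(m, 4)), 2L)
  expect_identical(max(label_components(m, 8)), 1L)
})

test_that("region mask combination matches set-algebra counts", {
  set.seed(8)
  dense <- matrix(runif(60 * 60) < 0.4, 60, 60)
  idc <- dense & matrix(runif(60 * 60) < 0.5, 60, 60)
  lab <- combine_region_masks(dense, idc)
  expect_identical(sum(lab == 2L), sum(idc))
  expect_identical(sum(lab == 1L), sum(dense & !idc))
  expect_identical(sum(lab == 0L), sum(!dense))
  # degenerate cases
  lab2 <- combine_region_masks(dense, dense)
  expect_identical(sum(lab2 == 1L), 0L)
  expect_warning(combine_region_masks(matrix(FALSE, 2, 2),
                                      matrix(TRUE, 2, 2)), "clipping")
})

test_that("polygon rasterization matches the area oracle", {
  # 1 x 1 mm square at 20 um pitch: 2500 px within one boundary row
  sq <- rbind(c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5), c(0.5, 1.5))
  m <- polygon_to_mask(sq, c(100, 100), c(20, 20))
  expect_lt(abs(sum(m) - 2500), 51)      # +/- one 50-px boundary row
  # zero-area polygon and fully-outside polygon give empty masks
  tri0 <- rbind(c(0.2, 0.2), c(0.8, 0.8), c(0.5, 0.5))
  expect_identical(sum(polygon_to_mask(tri0, c(50, 50), c(20, 20))), 0L)
  far <- rbind(c(10, 10), c(11, 10), c(10.5, 11))
  expect_identical(sum(polygon_to_mask(far, c(50, 50), c(20, 20))), 0L)
})

test_that("the mm2 converter uses the stated pitch", {
  expect_identical(area_mm2_to_px(4, c(20, 20)), 10000L)
})
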