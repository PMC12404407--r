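idc_cfg <- function(seed = 2, ...) {
  experiment_config(seed = seed,
                    meta = acquisition_meta(pitch_um = c(40, 40, 10)),
                    layer = compliant_layer(500), ...)
}

test_that("noiseless IDC experiment recovers region moduli and ordering", {
  rep <- run_idc_experiment(idc_cfg(noiseless = TRUE))
  rs <- rep$region_stats
  expect_equal(rs$elast_median_kpa[rs$region == "adipose"], 18,
               tolerance = 0.01)
  expect_equal(rs$elast_median_kpa[rs$region == "stroma"], 48,
               tolerance = 0.01)
  expect_equal(rs$elast_median_kpa[rs$region == "idc"], 230,
               tolerance = 0.01)
})

test_that("region elasticity ordering holds in every seeded noisy run", {
  for (seed in c(2, 5, 11)) {
    rep <- run_idc_experiment(idc_cfg(seed = seed))
    med <- setNames(rep$region_stats$elast_median_kpa,
                    rep$region_stats$region)
    expect_gt(med[["idc"]], med[["stroma"]])
    expect_gt(med[["stroma"]], med[["adipose"]])
    # |strain| ordering is the reverse
    st <- setNames(abs(rep$region_stats$strain_median),
                   rep$region_stats$region)
    expect_gt(st[["adipose"]], st[["stroma"]])
    expect_gt(st[["stroma"]], st[["idc"]])
  }
})

test_that("boundary FWHM grows strictly with the coupling kernel", {
  fwhms <- vapply(c(200, 400, 700), function(k) {
    rep <- run_idc_experiment(idc_cfg(seed = 2, noiseless = TRUE,
                                      coupling_fwhm_um = k))
    res <- rep$resolution
    res$fwhm_um[res$label == "stroma_adipose_strain"]
  }, numeric(1))
  expect_true(all(diff(fwhms) > 0))
})

test_that("experiment reports are deterministic under a fixed config", {
  r1 <- run_idc_experiment(idc_cfg(seed = 7))
  r2 <- run_idc_experiment(idc_cfg(seed = 7))
  expect_identical(r1$region_stats, r2$region_stats)
  expect_identical(r1$resolution, r2$resolution)
  d1 <- tempfile(); d2 <- tempfile()
  write_report_csv(r1, d1, "idc")
  write_report_csv(r2, d2, "idc")
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

duct_cfg <- function(seed = 3, ...) {
  experiment_config(seed = seed,
                    meta = acquisition_meta(pitch_um = c(50, 50, 25)),
                    layer = compliant_layer(500),
                    coupling_fwhm_um = 200, ...)
}

test_that("hollow ducts are masked out of strain and elasticity", {
  rep <- run_duct_experiment(duct_cfg(), fill = "hollow")
  expect_lt(rep$duct_stats$duct_valid_frac, 0.05)
  expect_equal(rep$duct_stats$bulk_elast_median_kpa, 58, tolerance = 0.1)
})

test_that("fluid-filled ducts deform more than the surrounding bulk", {
  rep <- run_duct_experiment(duct_cfg(), fill = "fluid")
  expect_gt(rep$duct_stats$duct_valid_frac, 0.5)
  expect_gt(abs(rep$duct_stats$duct_strain_median),
            abs(rep$duct_stats$bulk_strain_median))
  # the fluid lumen softens the cross-duct elasticity transition
  hol <- run_duct_experiment(duct_cfg(), fill = "hollow")
  f_fl <- rep$resolution$fwhm_um[rep$resolution$label ==
                                   "cross_duct_elasticity"]
  f_ho <- hol$resolution$fwhm_um[hol$resolution$label ==
                                   "cross_duct_elasticity"]
  expect_gte(f_fl, f_ho)
})

test_that("recovery experiment slabs agree with the ground-truth modulus", {
  r <- run_recovery_experiment(58, 25, shape = c(48, 48, 120),
                               pitch_um = c(15, 15, 3.5),
                               config = experiment_config(seed = 2),
                               central_px = 24, chunk_ny = 16)
  expect_equal(r$median_kpa, 58, tolerance = 0.05 * 58)
  expect_identical(dim(r$enface_mid), c(48L, 48L))
})
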