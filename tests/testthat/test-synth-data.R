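test_that("ground truth validates adduct fractions and non-negativity", {
  gt <- default_ground_truth(c(20, 20))
  expect_s3_class(gt, "ground_truth")
  expect_true(all(sort(unique(as.vector(gt$region_map))) == c(0, 1, 2)))
  bad_frac <- gt$adduct_fractions
  bad_frac$fraction[1] <- bad_frac$fraction[1] + 0.1
  expect_error(ground_truth(gt$region_map, gt$concentrations,
                            gt$response_factors, bad_frac),
               "sum to 1")
})

test_that("noise-free simulation plants exact per-pixel intensities", {
  fx <- noise_free_dataset(c(20L, 20L))
  ion <- adduct_mz("PC(34:1)", "[M+H]+")
  img <- extract_ion_image(fx$ds, ion, 5)
  wm <- fx$truth$region_map == 1
  expected <- 2000 * 9.07 * 0.35   # rf * conc * [M+H]+ fraction
  expect_true(all(abs(img$grid[wm] - expected) < 1e-9))
  # background pixels carry only matrix peaks
  bg_px <- which(as.vector(fx$truth$region_map) == 0L)[1]
  bg_rows <- fx$ds$peaks[fx$ds$peaks$pixel == bg_px, ]
  expect_true(all(bg_rows$mz < 620))
})

test_that("two seeds differ per pixel but agree in ROI expectation", {
  gt <- default_ground_truth(c(40, 40))
  mk <- function(seed) simulate_msi(
    msi_sim_config(grid_shape = c(40, 40), multiplicative_noise_cv = 0.1,
                   seed = seed), gt, default_panel())
  ds_a <- mk(1); ds_b <- mk(2)
  expect_false(identical(ds_a$peaks$intensity, ds_b$peaks$intensity))
  ion <- adduct_mz("PC(34:1)", "[M+H]+")
  r <- truth_roi(gt, 1, "WM")
  m_a <- roi_mean_intensity(extract_ion_image(ds_a, ion), r)
  m_b <- roi_mean_intensity(extract_ion_image(ds_b, ion), r)
  n <- nrow(r$pixels)
  se <- 2000 * 9.07 * 0.35 * 0.1 / sqrt(n)
  expect_lt(abs(m_a - m_b), 2 * 3 * se)
})

test_that("hotspot pixels are planted at the configured rate and scale", {
  gt <- default_ground_truth(c(100, 100))
  cfg <- msi_sim_config(grid_shape = c(100, 100),
                        multiplicative_noise_cv = 0.05,
                        hotspot_fraction = 0.01, hotspot_multiplier = 50,
                        seed = 5)
  ds <- simulate_msi(cfg, gt, default_panel())
  mask <- attr(ds, "hotspot_mask")
  n_tissue <- sum(gt$region_map > 0)
  expect_identical(sum(mask), as.integer(round(0.01 * n_tissue)))
  img <- extract_ion_image(ds, adduct_mz("PC(34:1)", "[M+H]+"))
  vals <- img$grid[cbind(ds$coords$y + 1L, ds$coords$x + 1L)]
  tissue <- as.vector(gt$region_map) > 0
  med <- stats::median(vals[tissue & !mask])
  expect_true(all(vals[mask] > 10 * med))
})

test_that("identical config and seed give byte-identical imzML", {
  gt <- default_ground_truth(c(15, 15))
  cfg <- msi_sim_config(grid_shape = c(15, 15), seed = 3)
  f1 <- tempfile(fileext = ".imzML"); f2 <- tempfile(fileext = ".imzML")
  write_imzml(simulate_msi(cfg, gt, default_panel()), f1)
  write_imzml(simulate_msi(cfg, gt, default_panel()), f2)
  for (ext in c("", ".ibd")) {
    a <- sub("\\.imzML$", paste0(".imzML", ext), f1)
  }
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(
    unname(tools::md5sum(sub("imzML$", "ibd", f1))),
    unname(tools::md5sum(sub("imzML$", "ibd", f2))))
})

test_that("dissected-extract amounts follow concentration x volume", {
  gt <- default_ground_truth(c(20, 20))
  ex <- simulate_lmd_extract(gt, lmd_region("WM", area = 1.0),
                             default_panel())
  sulf <- ex$mol[ex$lipid_name == "SHexCer(d18:1/24:1)"]
  expect_equal(sulf, 10.2e-9 * 1.0 * 0.020)   # 0.204 nmol
  ex2 <- simulate_lmd_extract(gt, lmd_region("WM", area = 2.0),
                              default_panel())
  expect_equal(ex2$mol, 2 * ex$mol)
  ex0 <- simulate_lmd_extract(
    gt, lmd_region("WM", area = 1, extraction_efficiency = 1e-12),
    default_panel())
  expect_true(all(ex0$mol < 1e-18))
  expect_error(simulate_lmd_extract(gt, lmd_region("GL", 1),
                                    default_panel()),
               "not present")
})

test_that("amounts are conserved across regions (noise-free bookkeeping)", {
  gt <- default_ground_truth(c(20, 20))
  areas <- c(WM = 0.7, ML = 1.3)
  total <- rowSums(vapply(names(areas), function(rg) {
    simulate_lmd_extract(gt, lmd_region(rg, areas[[rg]]),
                         default_panel())$mol
  }, numeric(6)))
  manual <- vapply(default_panel()$lipid_name, function(nm) {
    sum(vapply(names(areas), function(rg) {
      gt$concentrations$conc[gt$concentrations$lipid_name == nm &
                               gt$concentrations$region == rg] * 1e-9 *
        areas[[rg]] * 0.020
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(total), unname(manual))
})

test_that("a simulated Gaussian elution has the closed-form XIC area", {
  cfg <- lcms_sim_config(noise_cv = 0, rt_step = 0.005)
  run <- simulate_lcms_run(cfg, data.frame(
    lipid_name = "PC(34:1)", adduct = "[M+OAc]-", mol = 1e-10))
  ion <- adduct_mz("PC(34:1)", "[M+OAc]-")
  x <- extract_xic(run, ion, 5)
  area <- pracma::trapz(x$rt, x$intensity)
  expect_lt(abs(area - 100) / 100, 0.01)   # 1e12 * 1e-10 = 100
  # zero amount: nothing above the floor
  run0 <- simulate_lcms_run(cfg, data.frame(
    lipid_name = "PC(34:1)", adduct = "[M+OAc]-", mol = 0))
  expect_equal(max(extract_xic(run0, ion, 5)$intensity), 0)
})

test_that("an RT-offset interferent yields two resolved XIC peaks", {
  mz <- adduct_mz("PG(34:1)", "[M-H]-")$theoretical_mz
  cfg <- lcms_sim_config(noise_cv = 0,
                         interferents = data.frame(mz = mz, rt = 6.5,
                                                   area = 40))
  run <- simulate_lcms_run(cfg, data.frame(
    lipid_name = "PG(34:1)", adduct = "[M-H]-", mol = 1e-10))
  peaks <- detect_peaks(extract_xic(run, mz, 5))
  expect_identical(nrow(peaks), 2L)
  expect_equal(sort(peaks$apex_rt), c(3.5, 6.5), tolerance = 0.02)
})

test_that("the calibration series has the planted replicate structure", {
  cfg <- lcms_sim_config(noise_cv = 0)
  series <- simulate_calibration_series(cfg)
  expect_length(series, 9L)
  expect_true(all(vapply(series, function(l) length(l$runs), integer(1)) ==
                    3L))
  # noise-free: fitted slope recovers the area-per-mol ratio exactly
  curves <- fit_panel_calibrations(series, weights = "none")
  # analyte and IS share area_per_mol, so slope = extract_volume / IS mol
  expected_slope <- 20e-6 / 5e-10
  for (cv in curves) {
    expect_equal(cv$slope, expected_slope, tolerance = 1e-6)
    expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("a corrupted calibration level is flagged by its replicate CV", {
  cfg <- lcms_sim_config(noise_cv = 0.03, seed = 9)
  series <- simulate_calibration_series(cfg, corrupt_level = 4L,
                                        corrupt_cv = 0.5)
  expect_identical(attr(series, "corrupt_level"), 4L)
  curves <- fit_panel_calibrations(series)
  excl <- vapply(curves, function(cv) which(cv$levels$excluded),
                 integer(1))
  expect_true(all(excl == 4L))
})
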