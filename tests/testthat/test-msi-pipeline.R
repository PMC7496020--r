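test_that("imzML writing round-trips spectra, coordinates and metadata", {
  gt <- default_ground_truth(c(10, 10))
  ds <- simulate_msi(msi_sim_config(grid_shape = c(10, 10), seed = 2),
                     gt, default_panel())
  path <- tempfile(fileext = ".imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_identical(nrow(back$coords), 100L)
  expect_equal(back$peaks, ds$peaks)
  expect_equal(back$coords, ds$coords)
  expect_identical(back$polarity, ds$polarity)
  expect_equal(back$pixel_size, ds$pixel_size)
})

test_that("unreadable imzML inputs fail with actionable messages", {
  gt <- default_ground_truth(c(5, 5))
  ds <- simulate_msi(msi_sim_config(grid_shape = c(5, 5)), gt,
                     default_panel())
  path <- tempfile(fileext = ".imzML")
  write_imzml(ds, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "missing .ibd companion")

  cont <- tempfile(fileext = ".imzML")
  writeLines(gsub("IMS:1000031", "IMS:1000030", readLines(path)), cont)
  expect_error(read_imzml(cont), "continuous")

  bad <- tempfile(fileext = ".imzML")
  writeLines("<mzML><unclosed>", bad)
  expect_error(read_imzml(bad), "malformed imzML XML")
})

test_that("ion-image extraction honors the ppm window and aggregation", {
  mz0 <- 760
  peaks <- data.frame(
    pixel = c(1L, 1L, 2L, 3L),
    mz = c(mz0 * (1 + 3e-6), mz0 * (1 + 4e-6), mz0 * (1 + 10e-6), 500),
    intensity = c(10, 5, 7, 3))
  ds <- msi_dataset(data.frame(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L)),
                    peaks, pixel_size = 30)
  img_sum <- extract_ion_image(ds, mz0, 5, aggregation = "sum")
  expect_equal(img_sum$grid[1, 1], 15)   # both centroids inside
  expect_equal(img_sum$grid[1, 2], 0)    # +10 ppm is outside
  expect_equal(img_sum$grid[2, 1], 0)
  img_max <- extract_ion_image(ds, mz0, 5, aggregation = "max")
  expect_equal(img_max$grid[1, 1], 10)
})

test_that("ion-image extraction equals the brute-force per-pixel scan", {
  gt <- default_ground_truth(c(12, 12))
  ds <- simulate_msi(msi_sim_config(grid_shape = c(12, 12),
                                    multiplicative_noise_cv = 0.2,
                                    ppm_jitter_sd = 2, seed = 8),
                     gt, default_panel())
  for (nm in c("PC(34:1)", "PG(34:1)")) {
    for (agg in c("sum", "max")) {
      ion <- adduct_mz(nm, "[M+H]+")
      img <- extract_ion_image(ds, ion, 5, aggregation = agg)
      expect_equal(img$grid,
                   oracle_ion_image(ds, ion$theoretical_mz, 5, agg))
    }
  }
})

test_that("TIC normalization is scale-invariant and exact", {
  fx <- noise_free_dataset(c(10L, 10L))
  ds <- fx$ds
  # scale one pixel's spectrum by 7: its normalized spectrum is unchanged
  ds_scaled <- ds
  sel <- ds_scaled$peaks$pixel == 25L
  ds_scaled$peaks$intensity[sel] <- ds_scaled$peaks$intensity[sel] * 7
  n1 <- tic_normalize(ds)
  n2 <- tic_normalize(ds_scaled)
  expect_equal(n1$peaks$intensity[sel], n2$peaks$intensity[sel])
  # every nonzero pixel's TIC is 1 afterwards
  tics <- rowsum(n1$peaks$intensity, n1$peaks$pixel)
  expect_true(all(abs(tics - 1) < 1e-12))
})

test_that("hotspot clipping matches the interpolation quantile and is idempotent", {
  img <- structure(list(grid = matrix(1:100, 10, 10), mz = 700,
                        ppm_halfwidth = 5, aggregation = "sum",
                        pixel_size = 30), class = "ion_image")
  clipped <- remove_hotspots(img, 0.99)
  expect_equal(max(clipped$grid), 99.01)
  expect_equal(clipped$grid[1:98], as.numeric(1:98))
  # near-idempotent: a second pass can shave at most the interpolation
  # sliver between the two top order statistics
  expect_equal(remove_hotspots(clipped, 0.99)$grid, clipped$grid,
               tolerance = 1e-3)
  const <- img; const$grid[] <- 5
  expect_equal(remove_hotspots(const, 0.99)$grid, const$grid)
  expect_equal(remove_hotspots(img, 1)$grid, img$grid)
})

test_that("segmentation recovers the planted partition", {
  fx <- noise_free_dataset(c(20L, 20L), modality = "MALDI2")
  # noise-free features are exactly separable: no denoising needed (the
  # median filter would erode the thin white-matter lobes at this size)
  seg <- segment_msi(fx$ds, k = 3, denoise = "none", seed = 4)
  truthlab <- as.vector(fx$truth$region_map)
  expect_gt(adjusted_rand(as.vector(seg$labels), truthlab), 0.999)
  # determinism
  seg2 <- segment_msi(fx$ds, k = 3, denoise = "none", seed = 4)
  expect_identical(seg$labels, seg2$labels)
})

test_that("segmentation survives 10% multiplicative noise (ARI >= 0.9)", {
  gt <- default_ground_truth(c(30, 30))
  ds <- simulate_msi(msi_sim_config(grid_shape = c(30, 30),
                                    multiplicative_noise_cv = 0.1,
                                    modality = "MALDI2", seed = 6),
                     gt, default_panel())
  seg <- segment_msi(ds, k = 3, seed = 6)
  expect_gt(adjusted_rand(as.vector(seg$labels),
                          as.vector(gt$region_map)), 0.9)
})

test_that("ROIs from segments have the right area and compose disjointly", {
  labels <- matrix(0L, 25, 20)
  labels[1:10, ] <- 1L
  labels[11:15, 1:10] <- 2L
  seg <- structure(list(labels = labels, k = 3L, seed = 1L),
                   class = "segmentation_map")
  r1 <- roi_from_segments(seg, 1L, "A", pixel_size = 30)
  expect_identical(nrow(r1$pixels), 200L)
  expect_equal(r1$area, 200 * 0.0009)
  expect_error(roi_from_segments(seg, 7L, "X", 30), "not in segmentation")
  r_union <- roi_from_segments(seg, c(1L, 2L), "AB", 30)
  r2 <- roi_from_segments(seg, 2L, "B", 30)
  expect_identical(nrow(r_union$pixels), nrow(r1$pixels) + nrow(r2$pixels))
  expect_equal(r_union$area, r1$area + r2$area)
})

test_that("ROI means include zeros and ignore pixel order", {
  grid <- matrix(0, 4, 4)
  grid[1, 1] <- 2; grid[2, 2] <- 4
  img <- structure(list(grid = grid, mz = 700, ppm_halfwidth = 5,
                        aggregation = "sum", pixel_size = 30),
                   class = "ion_image")
  r <- roi(data.frame(x = c(0L, 1L), y = c(0L, 1L)), "r", 30)
  expect_equal(roi_mean_intensity(img, r), 3)
  r_rev <- roi(data.frame(x = c(1L, 0L), y = c(1L, 0L)), "r", 30)
  expect_equal(roi_mean_intensity(img, r_rev), 3)
  r_zero <- roi(data.frame(x = 3L, y = 3L), "z", 30)
  expect_equal(roi_mean_intensity(img, r_zero), 0)
})

test_that("summed adduct intensity recovers rf x concentration exactly", {
  fx <- noise_free_dataset(c(20L, 20L))
  r <- truth_roi(fx$truth, 1, "WM")
  pos <- c("[M+H]+", "[M+Na]+", "[M+K]+")
  # degenerate sum: single adduct equals the plain ROI mean
  ion <- adduct_mz("PC(34:1)", "[M+H]+")
  expect_equal(
    summed_adduct_intensity(fx$ds, "PC(34:1)", "[M+H]+", r),
    roi_mean_intensity(extract_ion_image(fx$ds, ion, 5), r))
  # full sum: adduct fractions sum to 1, so rf * conc comes back exactly
  for (nm in c("PC(34:1)", "PE(34:1)", "PG(34:1)")) {
    rf <- fx$truth$response_factors
    planted <- rf$rf[rf$lipid_name == nm & rf$region == "WM" &
                       rf$modality == "MALDI" & rf$polarity == "+"]
    conc <- fx$truth$concentrations
    planted_c <- conc$conc[conc$lipid_name == nm & conc$region == "WM"]
    expect_equal(summed_adduct_intensity(fx$ds, nm, pos, r),
                 planted * planted_c, tolerance = 1e-12)
  }
})
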