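test_that("XIC extraction reproduces the sampled elution profile", {
  run <- gaussian_run(amp = 1000, mu = 5, sigma = 0.05, mz = 700)
  x <- extract_xic(run, 700, 5)
  expect_length(x$intensity, length(run$rt_grid))
  sel <- abs(x$rt - 5) <= 0.25
  expect_equal(x$intensity[sel],
               1000 * exp(-(x$rt[sel] - 5)^2 / (2 * 0.05^2)))
  # outside any window: all zero
  expect_true(all(extract_xic(run, 900, 5)$intensity == 0))
  # narrowing the window never increases any point
  wide <- extract_xic(run, 700.002, 5)$intensity
  narrow <- extract_xic(run, 700.002, 2.5)$intensity
  expect_true(all(narrow <= wide))
})

test_that("peak detection finds isolated Gaussians and nothing in noise-free zeros", {
  run <- gaussian_run()
  x <- extract_xic(run, 700, 5)
  p <- detect_peaks(x)
  expect_identical(nrow(p), 1L)
  expect_lt(abs(p$apex_rt - 5), 0.0051)
  # two resolved Gaussians
  run2 <- chrom_run(rbind(
    data.frame(rt = gaussian_run(mu = 4)$points$rt, mz = 700,
               intensity = gaussian_run(mu = 4)$points$intensity),
    data.frame(rt = gaussian_run(mu = 7)$points$rt, mz = 700,
               intensity = gaussian_run(mu = 7)$points$intensity)),
    rt_grid = gaussian_run()$rt_grid)
  p2 <- detect_peaks(extract_xic(run2, 700, 5))
  expect_identical(nrow(p2), 2L)
  flat <- structure(list(rt = seq(0, 10, 0.01),
                         intensity = numeric(1001), mz = 700,
                         ppm_halfwidth = 5), class = "xic")
  expect_identical(nrow(detect_peaks(flat)), 0L)
})

test_that("trapezoidal integration matches closed forms", {
  run <- gaussian_run(amp = 1000, sigma = 0.05, rt_step = 0.002)
  x <- extract_xic(run, 700, 5)
  p <- detect_peaks(x)
  a <- integrate_peak(x, p[1, ])
  expect_lt(abs(a - 1000 * 0.05 * sqrt(2 * pi)) / (125.33), 0.01)
  # fine-grid numerical oracle over the same bounds, within 0.1%
  fine <- seq(p$left_rt[1], p$right_rt[1], length.out = 20001)
  oracle <- sum(1000 * exp(-(fine - 5)^2 / (2 * 0.05^2))) * diff(fine[1:2])
  expect_lt(abs(a - oracle) / oracle, 0.001)
  # rectangle: exact
  rect <- structure(list(rt = seq(0, 1, 0.1), intensity = rep(3, 11),
                         mz = 1, ppm_halfwidth = 5), class = "xic")
  expect_equal(integrate_peak(rect, list(left_rt = 0, right_rt = 1)), 3)
  expect_equal(integrate_peak(rect, list(left_rt = 0.5, right_rt = 0.5)), 0)
  expect_error(integrate_peak(rect, list(left_rt = 1, right_rt = 0)),
               "inverted")
})

test_that("calibration fitting excludes noisy levels and fits the rest", {
  conc <- 10^seq(-7, -4, length.out = 5)
  exact <- lapply(conc, function(cc) rep(1e4 * cc, 3))
  fit <- fit_calibration(exact, conc)
  expect_equal(fit$slope, 1e4)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_false(any(fit$levels$excluded))

  # corrupt one level: excluded, fit unchanged
  noisy <- exact
  noisy[[3]] <- 1e4 * conc[3] * c(0.3, 1.0, 2.2)
  fit2 <- fit_calibration(noisy, conc)
  expect_identical(which(fit2$levels$excluded), 3L)
  expect_equal(fit2$slope, fit$slope)

  # two levels: line through the means
  fit3 <- fit_calibration(list(c(1, 1), c(3, 3)), c(0.1, 0.3))
  expect_equal(unname(coef(fit3)), c(0, 10))

  expect_error(
    fit_calibration(list(c(1, 5), c(2, 9)), c(0.1, 0.3)),
    "fewer than 2")
})

test_that("the calibration object behaves like a fitted model", {
  conc <- c(1e-6, 1e-5, 1e-4)
  fit <- fit_calibration(lapply(conc, function(cc) rep(2e4 * cc, 3)), conc,
                         lipid = "PC(34:1)")
  expect_equal(unname(coef(fit)), c(0, 2e4), tolerance = 1e-9)
  expect_equal(predict(fit, area_ratio = 0.05), 2.5e-6)
  expect_equal(predict(fit, area_ratio = fit$intercept), 0)
  expect_warning(neg <- predict(fit, area_ratio = -1), "clamped")
  expect_equal(neg, 0)
  expect_length(residuals(fit), 3L)
  expect_output(print(fit), "slope")
})

test_that("back-calculation recovers planted extract concentrations", {
  cfg <- lcms_sim_config(noise_cv = 0)
  series <- simulate_calibration_series(cfg)
  curves <- fit_panel_calibrations(series)
  panel <- default_panel()
  planted <- 3.3e-6
  run <- simulate_lcms_run(cfg, calibration_amounts_for_test(cfg, panel,
                                                             planted))
  for (i in c(1L, 6L)) {   # a PG and the sulfatide
    ion <- adduct_mz(panel$lipid_name[i], panel$quant_adduct[i])
    is_ion <- adduct_mz(panel$is_name[i], panel$quant_adduct[i])
    est <- quantify_extract(run, curves[[panel$lipid_name[i]]], ion, is_ion)
    expect_lt(abs(est - planted) / planted, 0.01)
  }
  # monotonicity: more analyte never back-calculates lower (noise-free)
  ests <- vapply(c(1e-7, 1e-6, 1e-5), function(cc) {
    r <- simulate_lcms_run(cfg, calibration_amounts_for_test(cfg, panel, cc))
    ion <- adduct_mz(panel$lipid_name[1], panel$quant_adduct[1])
    is_ion <- adduct_mz(panel$is_name[1], panel$quant_adduct[1])
    quantify_extract(r, curves[[panel$lipid_name[1]]], ion, is_ion)
  }, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("a missing internal standard is a hard error", {
  cfg <- lcms_sim_config(noise_cv = 0)
  series <- simulate_calibration_series(cfg)
  curves <- fit_panel_calibrations(series)
  panel <- default_panel()
  # run without the IS spike
  run <- simulate_lcms_run(cfg, data.frame(
    lipid_name = "PG(34:1)", adduct = "[M-H]-", mol = 1e-12))
  ion <- adduct_mz("PG(34:1)", "[M-H]-")
  is_ion <- adduct_mz("PG(15:0/18:1)-d7", "[M-H]-")
  expect_error(quantify_extract(run, curves[["PG(34:1)"]], ion, is_ion),
               "internal-standard peak not found")
})

test_that("tissue concentration arithmetic and units are exact", {
  q <- tissue_concentration(5e-6, area = 2.5)
  expect_equal(q$amount, 0.1)              # nmol
  expect_equal(q$tissue_volume, 0.05)      # mm^3
  expect_equal(q$tissue_concentration, 2)  # nmol/mm^3
  expect_equal(q$tissue_concentration,
               q$amount / q$tissue_volume)
  q2 <- tissue_concentration(5e-6, area = 5)
  expect_equal(q2$tissue_concentration, 1)
})

test_that("interference screening applies the 5% contribution rule", {
  mz <- adduct_mz("PG(34:1)", "[M-H]-")$theoretical_mz
  mk_run <- function(inter_area) {
    cfg <- lcms_sim_config(noise_cv = 0,
                           interferents = data.frame(mz = mz, rt = 7,
                                                     area = inter_area))
    simulate_lcms_run(cfg, data.frame(lipid_name = "PG(34:1)",
                                      adduct = "[M-H]-", mol = 1e-12))
  }
  # main area = 1e12 * 1e-12 = 1; 4% passes, 6% is flagged
  rep_clean <- interference_check(mk_run(0.04), mz,
                                  main_rt_window = c(3, 4))
  expect_true(rep_clean$clean)
  expect_equal(rep_clean$interferents$contribution, 0.04, tolerance = 0.01)
  rep_flag <- interference_check(mk_run(0.06), mz,
                                 main_rt_window = c(3, 4))
  expect_false(rep_flag$clean)
  # no secondary peaks at all
  cfg0 <- lcms_sim_config(noise_cv = 0)
  run0 <- simulate_lcms_run(cfg0, data.frame(lipid_name = "PG(34:1)",
                                             adduct = "[M-H]-",
                                             mol = 1e-12))
  rep0 <- interference_check(run0, mz, main_rt_window = c(3, 4))
  expect_true(rep0$clean)
  expect_identical(nrow(rep0$interferents), 0L)
  expect_error(interference_check(run0, mz, main_rt_window = c(8, 9)),
               "no main peak")
})
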