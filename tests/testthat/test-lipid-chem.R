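test_that("shorthand names parse to class, totals and chains", {
  cases <- list(
    list("PC(34:1)", "PC", 34L, 1L, NULL),
    list("PC(38:4)", "PC", 38L, 4L, NULL),
    list("PE(16:0/18:1)", "PE", 34L, 1L, rbind(c(16L, 0L), c(18L, 1L))),
    list("PG(16:0/18:1)", "PG", 34L, 1L, rbind(c(16L, 0L), c(18L, 1L)))
  )
  for (cs in cases) {
    lip <- parse_lipid_name(cs[[1]])
    expect_s3_class(lip, "lipid_species")
    expect_identical(lip$lipid_class, cs[[2]])
    expect_identical(lip$total_acyl_carbons, cs[[3]])
    expect_identical(lip$total_double_bonds, cs[[4]])
    if (!is.null(cs[[5]])) expect_equal(unname(lip$chains), cs[[5]])
  }
})

test_that("sulfatide spellings are aliases and totals include the sphingoid", {
  a <- parse_lipid_name("SHexCer(d18:1/24:1)")
  b <- parse_lipid_name("(3′-sulfo)Galβ1-1Cer(d18:1/24:1)")
  expect_identical(a$name, b$name)
  expect_identical(a$lipid_class, "SHexCer")
  expect_identical(a$sphingoid, c(18L, 1L))
  expect_identical(a$total_acyl_carbons, 42L)
  expect_identical(a$total_double_bonds, 2L)
})

test_that("labeled internal standards carry their deuterium count", {
  lip <- parse_lipid_name("PC(15:0/18:1)-d7")
  expect_identical(lip$label_extra_neutrons, 7L)
  expect_identical(lip$total_acyl_carbons, 33L)
})

test_that("malformed names raise errors naming the offending token", {
  expect_error(parse_lipid_name("PX(34:1)"), "unknown lipid class 'PX'")
  expect_error(parse_lipid_name("PC(34:x)"), "malformed")
  expect_error(parse_lipid_name("PC34:1"), "malformed")
  expect_error(parse_lipid_name("PC(34:40)"), "double bonds")
})

test_that("formula builder reproduces diacyl and sulfatide compositions", {
  f <- build_formula(parse_lipid_name("PC(34:1)"))
  expect_identical(unclass(f)[c("C", "H", "N", "O", "P")],
                   c(C = 42L, H = 82L, N = 1L, O = 8L, P = 1L))
  f2 <- build_formula(parse_lipid_name("SHexCer(d18:1/24:1)"))
  expect_identical(unclass(f2)[c("C", "H", "N", "O", "S")],
                   c(C = 48L, H = 91L, N = 1L, O = 11L, S = 1L))
  f3 <- build_formula(parse_lipid_name("PE(40:6)"))
  expect_identical(unclass(f3)[["C"]], 45L)
  expect_identical(unclass(f3)[["H"]], 78L)
  # a degenerate composition (only constructible by hand: the parser already
  # rejects D > C) must fail rather than return a negative hydrogen count
  bad <- structure(list(lipid_class = "PE", total_acyl_carbons = 4L,
                        total_double_bonds = 10L, chains = NULL,
                        sphingoid = NULL, label_extra_neutrons = 0L,
                        name = "PE(4:10)"), class = "lipid_species")
  expect_error(build_formula(bad), "over-unsaturated")
})

test_that("monoisotopic masses match the independent reference calculator", {
  for (nm in names(reference_masses)) {
    m <- monoisotopic_mass(build_formula(parse_lipid_name(nm)))
    expect_lt(abs(m - reference_masses[[nm]]), 0.001)
  }
  empty <- structure(integer(0), class = "molecular_formula")
  expect_identical(monoisotopic_mass(empty), 0)
})

test_that("mass table constants are self-consistent", {
  mt <- mass_table()
  expect_lt(abs(mt$proton_mass -
                  (mt$element_masses[["H"]] - mt$electron_mass)), 1e-9)
  expect_true(all(mt$element_masses > 0))
  tab <- adduct_table()
  na_h <- tab$mass_delta[tab$name == "[M+Na]+"] -
    tab$mass_delta[tab$name == "[M+H]+"]
  expect_lt(abs(na_h - 21.98194), 1e-4)
})

test_that("adduct m/z ordering and gaps hold for every panel lipid", {
  for (nm in c("PG(34:1)", "PE(34:1)", "PC(34:1)", "PC(38:4)", "PC(40:6)")) {
    h <- adduct_mz(nm, "[M+H]+")$theoretical_mz
    na <- adduct_mz(nm, "[M+Na]+")$theoretical_mz
    k <- adduct_mz(nm, "[M+K]+")$theoretical_mz
    dep <- adduct_mz(nm, "[M-H]-")$theoretical_mz
    expect_true(k > na && na > h)
    expect_lt(abs((na - h) - 21.98194), 1e-4)
    expect_lt(abs((k - na) - 15.97394), 1e-4)
    expect_lt(abs((h - dep) - 2 * mass_table()$proton_mass), 1e-9)
  }
})

test_that("deuterium substitution shifts mass by exactly k * (D - H)", {
  mt <- mass_table()
  d3 <- monoisotopic_mass(build_formula(
    parse_lipid_name("SHexCer(d18:1/18:0)-d3")))
  d0 <- monoisotopic_mass(build_formula(
    parse_lipid_name("SHexCer(d18:1/18:0)")))
  expect_equal(d3 - d0,
               3 * (mt$element_masses[["D"]] - mt$element_masses[["H"]]))
})

test_that("ppm windows are symmetric in relative terms and scale with m/z", {
  w <- ppm_window(800, 5)
  expect_equal(unname(w), c(799.996, 800.004))
  expect_equal(unname(ppm_window(123.4, 0)), c(123.4, 123.4))
  w2 <- ppm_window(1600, 5)
  expect_equal(unname(diff(w2)), 2 * unname(diff(w)))
})

test_that("near-isobar enumeration matches the exhaustive double-loop oracle", {
  classes <- "PC"; adducts <- c("[M+H]+", "[M+Na]+")
  cr <- c(32, 38); dr <- c(0, 5); tol <- 5
  hits <- find_near_isobars(classes, adducts, cr, dr, tol)
  expect_identical(pair_keys(hits), oracle_near_isobars(classes, adducts,
                                                        cr, dr, tol))
  expect_identical(nrow(find_near_isobars(classes, adducts, cr, dr, 0)), 0L)
})

test_that("the sodiated/protonated PC family sits ~2.4 mDa apart", {
  hits <- find_near_isobars("PC", c("[M+H]+", "[M+Na]+"), c(30, 44),
                            c(0, 6), 5)
  expect_gt(nrow(hits), 0L)
  fam <- hits[hits$adduct_a != hits$adduct_b, ]
  expect_true(all(abs(fam$delta_mda - 2.4057) < 0.001))
  # the family is the (+2 carbons, +3 double bonds) relation
  comp <- function(nm) as.integer(regmatches(nm, regexec(
    "\\((\\d+):(\\d+)\\)", nm))[[1]][2:3])
  for (i in seq_len(nrow(fam))) {
    a <- comp(fam$name_a[i]); b <- comp(fam$name_b[i])
    expect_identical(abs(a - b), c(2L, 3L))
  }
  expect_false(any(abs(hits$delta_mda - 2015.65) < 5))
})

test_that("resolvability follows the FT resolution scaling", {
  # FWHM at m/z 866.66 with R200 = 280k is ~6.4 mDa
  expect_false(resolvable(866.660, 866.660 + 0.002406, 280000))
  expect_true(resolvable(866.660, 866.660 + 0.028, 280000))
  expect_false(resolvable(500, 500, 1e6))
})
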