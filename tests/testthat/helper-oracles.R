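# Independent oracles and shared fixtures, built in code at test time.

# Reference monoisotopic neutral masses for the target panel and internal
# standards, frozen from an independent formula/mass calculator.
reference_masses <- c(
  "PC(34:1)" = 759.57781,
  "PC(38:4)" = 809.59346,
  "PC(40:6)" = 833.59346,
  "PE(34:1)" = 717.53086,
  "PE(40:6)" = 791.54651,
  "PG(34:1)" = 748.52544,
  "SHexCer(d18:1/24:1)" = 889.63128,
  "SHexCer(d18:1/18:0)" = 807.55303
)

# Brute-force ion image: per-pixel linear scan, no shared code with
# extract_ion_image beyond the dataset container.
oracle_ion_image <- function(ds, mz, ppm, aggregation = "sum") {
  lo <- mz * (1 - ppm * 1e-6)
  hi <- mz * (1 + ppm * 1e-6)
  sh <- c(max(ds$coords$y) + 1L, max(ds$coords$x) + 1L)
  grid <- matrix(0, sh[1], sh[2])
  for (p in seq_len(nrow(ds$coords))) {
    rows <- ds$peaks[ds$peaks$pixel == p, ]
    inwin <- rows$mz >= lo & rows$mz <= hi
    v <- if (!any(inwin)) 0 else if (aggregation == "sum") {
      sum(rows$intensity[inwin])
    } else {
      max(rows$intensity[inwin])
    }
    grid[ds$coords$y[p] + 1L, ds$coords$x[p] + 1L] <- v
  }
  grid
}

# Exhaustive double-loop near-isobar oracle over the same composition grid.
oracle_near_isobars <- function(classes, adducts, carbon_range, db_range,
                                tol_mda) {
  specs <- list()
  for (cl in classes) for (cc in carbon_range[1]:carbon_range[2]) {
    for (dd in db_range[1]:db_range[2]) {
      if (dd > cc) next
      for (ad in adducts) {
        specs[[length(specs) + 1L]] <- list(
          name = sprintf("%s(%d:%d)", cl, cc, dd), adduct = ad,
          mz = adduct_mz(sprintf("%s(%d:%d)", cl, cc, dd), ad)$theoretical_mz)
      }
    }
  }
  pairs <- character(0)
  n <- length(specs)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- specs[[i]]; b <- specs[[j]]
    if (a$name == b$name && a$adduct == b$adduct) next
    if (abs(a$mz - b$mz) <= tol_mda * 1e-3) {
      key <- sort(c(paste(a$name, a$adduct), paste(b$name, b$adduct)))
      pairs <- c(pairs, paste(key, collapse = " | "))
    }
  }
  sort(unique(pairs))
}

pair_keys <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  keys <- vapply(seq_len(nrow(hits)), function(i) {
    key <- sort(c(paste(hits$name_a[i], hits$adduct_a[i]),
                  paste(hits$name_b[i], hits$adduct_b[i])))
    paste(key, collapse = " | ")
  }, character(1))
  sort(unique(keys))
}

# Small noise-free dataset used across imaging tests.
noise_free_dataset <- function(shape = c(20L, 20L), modality = "MALDI") {
  gt <- default_ground_truth(shape)
  cfg <- msi_sim_config(grid_shape = shape, multiplicative_noise_cv = 0,
                        ppm_jitter_sd = 0, modality = modality)
  list(truth = gt, ds = simulate_msi(cfg, gt, default_panel()))
}

truth_roi <- function(gt, code, name, pixel_size = 30) {
  px <- which(gt$region_map == code, arr.ind = TRUE)
  roi(data.frame(x = px[, 2] - 1L, y = px[, 1] - 1L), name = name,
      pixel_size = pixel_size)
}

# Adjusted Rand index between two label vectors (closed-form from the
# contingency table) — independent of any clustering code under test.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# One Gaussian-peak chromatogram run on a dense grid.
gaussian_run <- function(amp = 1000, mu = 5, sigma = 0.05, mz = 700,
                         rt_step = 0.005, rt_range = c(0, 10)) {
  rt <- seq(rt_range[1], rt_range[2], by = rt_step)
  sel <- abs(rt - mu) <= 6 * sigma
  chrom_run(data.frame(rt = rt[sel], mz = mz,
                       intensity = amp * exp(-(rt[sel] - mu)^2 /
                                               (2 * sigma^2))),
            rt_grid = rt, polarity = "-", sample_id = "gauss")
}

calibration_amounts_for_test <- function(cfg, panel, conc) {
  msiresponse:::calibration_amounts(cfg, panel, conc)
}
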