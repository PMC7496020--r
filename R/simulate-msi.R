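#' Configuration for the synthetic MSI generator
#'
#' @param grid_shape `c(rows, cols)` of the pixel grid; must match the
#'   ground-truth region map it is used with.
#' @param pixel_size Pixel edge length, micrometers (30 for the
#'   undersampling acquisitions, 20 for the comparative images).
#' @param ppm_jitter_sd Gaussian mass-error standard deviation, ppm.
#' @param multiplicative_noise_cv Coefficient of variation of the lognormal
#'   multiplicative intensity noise (per peak per pixel).
#' @param additive_noise_level Mean of the half-normal additive baseline
#'   intensity noise; 0 disables it.
#' @param matrix_peaks Data frame `mz`, `intensity` of matrix-derived peaks
#'   present in every pixel (tissue or background).
#' @param hotspot_fraction Fraction of tissue pixels scaled up as hotspots.
#' @param hotspot_multiplier Intensity multiplier for hotspot pixels (>= 1).
#' @param modality `"MALDI"` or `"MALDI2"`.
#' @param polarity `"+"` or `"-"`.
#' @param seed Integer RNG seed.
#' @return Object of class `msi_sim_config`.
#' @export
msi_sim_config <- function(grid_shape = c(100L, 100L), pixel_size = 30,
                           ppm_jitter_sd = 1, multiplicative_noise_cv = 0.1,
                           additive_noise_level = 0,
                           matrix_peaks = default_matrix_peaks(),
                           hotspot_fraction = 0, hotspot_multiplier = 1,
                           modality = "MALDI", polarity = "+", seed = 1L) {
  stopifnot(all(grid_shape > 0), pixel_size > 0, ppm_jitter_sd >= 0,
            multiplicative_noise_cv >= 0, additive_noise_level >= 0,
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            hotspot_multiplier >= 1,
            modality %in% c("MALDI", "MALDI2"), polarity %in% c("+", "-"))
  out <- list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
              ppm_jitter_sd = ppm_jitter_sd,
              multiplicative_noise_cv = multiplicative_noise_cv,
              additive_noise_level = additive_noise_level,
              matrix_peaks = matrix_peaks,
              hotspot_fraction = hotspot_fraction,
              hotspot_multiplier = hotspot_multiplier,
              modality = modality, polarity = polarity,
              seed = as.integer(seed))
  class(out) <- "msi_sim_config"
  out
}

#' @rdname msi_sim_config
#' @export
default_matrix_peaks <- function() {
  data.frame(mz = c(551.24, 568.27, 616.18), intensity = c(300, 200, 120))
}

# lognormal factors with mean 1 and the requested CV
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a ground-truthed MSI dataset
#'
#' Every pixel receives a centroid spectrum. For each panel ion the expected
#' intensity in a tissue pixel is
#' `response_factor(lipid, region, modality) * concentration(lipid, region)
#' * adduct_fraction`, multiplied by lognormal noise with the configured CV;
#' the centroid m/z is displaced by Gaussian ppm jitter. Matrix peaks are
#' added everywhere; background pixels carry only matrix peaks (plus
#' additive noise). A seeded random subset of tissue pixels is scaled by the
#' hotspot multiplier; the hotspot mask is returned as an attribute so tests
#' can check hotspot handling against the planted truth. Deterministic for a
#' fixed seed.
#'
#' @param config An [msi_sim_config()].
#' @param truth A [ground_truth()] whose `region_map` matches
#'   `config$grid_shape`.
#' @param panel Panel data frame (see [default_panel()]); ions are expanded
#'   for `config$polarity`.
#' @return An [msi_dataset()] with attributes `hotspot_mask` (logical
#'   vector over pixels) and `truth_seed`.
#' @examples
#' gt <- default_ground_truth(c(20, 20))
#' ds <- simulate_msi(msi_sim_config(grid_shape = c(20, 20)), gt,
#'                    default_panel())
#' ds
#' @export
simulate_msi <- function(config, truth, panel = default_panel()) {
  stopifnot(inherits(config, "msi_sim_config"),
            inherits(truth, "ground_truth"))
  if (!identical(dim(truth$region_map), as.integer(config$grid_shape))) {
    stop("config grid_shape does not match truth region_map", call. = FALSE)
  }
  ions <- panel_ions(panel, config$polarity)
  frac <- truth$adduct_fractions
  key <- paste(ions$lipid_name, ions$adduct)
  fr <- frac$fraction[match(key, paste(frac$lipid_name, frac$adduct))]
  if (anyNA(fr)) {
    stop("panel ion(s) missing from truth adduct fractions: ",
         paste(key[is.na(fr)], collapse = ", "), call. = FALSE)
  }
  ions$fraction <- fr

  rm_ <- truth$region_map
  nr <- nrow(rm_); nc <- ncol(rm_)
  # pixel order: row-major over the grid (y by row, x by column), 0-based
  coords <- data.frame(x = rep(0:(nc - 1L), each = nr),
                       y = rep(0:(nr - 1L), times = nc))
  region_of_pixel <- as.vector(rm_)   # column-major == (x, y) order above
  npix <- length(region_of_pixel)

  regions <- sort(unique(region_of_pixel[region_of_pixel > 0L]))
  region_name <- function(r) c("WM", "ML", "R3", "R4")[r]

  set.seed(config$seed)
  # expected intensity per ion x region
  exp_int <- matrix(0, nrow = nrow(ions), ncol = max(c(regions, 1L)))
  for (r in regions) {
    rn <- region_name(r)
    for (i in seq_len(nrow(ions))) {
      conc <- truth_conc(truth, ions$lipid_name[i], rn)
      rf <- truth_rf(truth, ions$lipid_name[i], rn, config$modality,
                     config$polarity)
      exp_int[i, r] <- rf * conc * ions$fraction[i]
    }
  }

  tissue <- which(region_of_pixel > 0L)
  n_hot <- round(config$hotspot_fraction * length(tissue))
  hot_idx <- if (n_hot > 0) sample(tissue, n_hot) else integer(0)
  hotspot <- logical(npix)
  hotspot[hot_idx] <- TRUE
  scale_px <- ifelse(hotspot, config$hotspot_multiplier, 1)

  blocks <- vector("list", nrow(ions) + 1L)
  for (i in seq_len(nrow(ions))) {
    mu <- exp_int[i, pmax(region_of_pixel, 1L)]
    mu[region_of_pixel == 0L] <- 0
    present <- which(mu > 0)
    if (!length(present)) next
    inten <- mu[present] * lognormal_noise(length(present),
                                           config$multiplicative_noise_cv) *
      scale_px[present]
    mzs <- ions$mz[i] * (1 + stats::rnorm(length(present), 0,
                                          config$ppm_jitter_sd) * 1e-6)
    blocks[[i]] <- data.frame(pixel = present, mz = mzs, intensity = inten)
  }
  # matrix peaks in every pixel
  mp <- config$matrix_peaks
  if (nrow(mp) > 0) {
    mat <- data.frame(
      pixel = rep(seq_len(npix), times = nrow(mp)),
      mz = rep(mp$mz, each = npix) *
        (1 + stats::rnorm(npix * nrow(mp), 0, config$ppm_jitter_sd) * 1e-6),
      intensity = rep(mp$intensity, each = npix) *
        lognormal_noise(npix * nrow(mp), config$multiplicative_noise_cv) *
        scale_px
    )
    blocks[[nrow(ions) + 1L]] <- mat
  }
  peaks <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (config$additive_noise_level > 0) {
    peaks$intensity <- peaks$intensity +
      abs(stats::rnorm(nrow(peaks), 0, config$additive_noise_level))
  }

  ds <- msi_dataset(coords, peaks, pixel_size = config$pixel_size,
                    polarity = config$polarity, modality = config$modality)
  attr(ds, "hotspot_mask") <- hotspot
  attr(ds, "truth_seed") <- truth$seed
  ds
}
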