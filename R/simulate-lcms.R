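#' Configuration for the synthetic LC-MS generator
#'
#' Emulates HILIC class separation: every lipid class elutes in its own
#' retention window, and each injected ion produces a Gaussian peak whose
#' area is proportional to the injected amount. Negative ion mode
#' throughout, matching the quantification method (deprotonated species for
#' PE, PG and the sulfatide; acetate adduct for PC).
#'
#' @param class_rt Named numeric vector, retention time (min) per lipid
#'   class.
#' @param peak_sigma Gaussian peak width (standard deviation), min.
#' @param area_per_mol Detector response: XIC peak area
#'   (intensity x min) per mol injected. Single number or named per class.
#' @param is_amounts Named numeric vector, mol of internal standard per
#'   vial per class (the 5 uL IS spike; default 5e-10 mol = 5 uL of a
#'   1e-4 mol/L solution).
#' @param extract_volume Final extract volume, L (default 20e-6: the 20 uL
#'   of chloroform the dried extract is dissolved in).
#' @param calibration_concentrations Strictly positive, distinct mol/L
#'   levels; default nine log-spaced dilutions of the 1e-4 mol/L stock down
#'   to 1e-7 mol/L.
#' @param noise_cv CV of the lognormal peak-area noise.
#' @param interferents Optional data frame `mz`, `rt`, `area` of extra
#'   (isobaric) peaks injected into every run.
#' @param rt_range,rt_step Scan-time grid, min.
#' @param seed Integer RNG seed.
#' @return Object of class `lcms_sim_config`.
#' @export
lcms_sim_config <- function(class_rt = c(PG = 3.5, PE = 5.0, PC = 7.0,
                                         SHexCer = 9.0),
                            peak_sigma = 0.05, area_per_mol = 1e12,
                            is_amounts = c(PG = 5e-10, PE = 5e-10,
                                           PC = 5e-10, SHexCer = 5e-10),
                            extract_volume = 20e-6,
                            calibration_concentrations =
                              10^seq(-7, -4, length.out = 9),
                            noise_cv = 0.05, interferents = NULL,
                            rt_range = c(0, 12), rt_step = 0.02,
                            seed = 1L) {
  stopifnot(peak_sigma > 0, extract_volume > 0, noise_cv >= 0,
            all(calibration_concentrations > 0),
            !anyDuplicated(calibration_concentrations),
            rt_step > 0, diff(rt_range) > 0)
  out <- list(class_rt = class_rt, peak_sigma = peak_sigma,
              area_per_mol = area_per_mol, is_amounts = is_amounts,
              extract_volume = extract_volume,
              calibration_concentrations =
                sort(calibration_concentrations),
              noise_cv = noise_cv, interferents = interferents,
              rt_range = rt_range, rt_step = rt_step,
              seed = as.integer(seed))
  class(out) <- "lcms_sim_config"
  out
}

class_area_per_mol <- function(config, cls) {
  a <- config$area_per_mol
  if (length(a) == 1L && is.null(names(a))) return(a)
  if (!cls %in% names(a)) stop("no area_per_mol for class ", cls,
                               call. = FALSE)
  a[[cls]]
}

#' Simulate one LC-MS chromatogram run
#'
#' Each entry of `amounts` elutes as a Gaussian at its lipid class's
#' retention time with total XIC area `area_per_mol * mol`, multiplied by
#' lognormal noise; scans are emitted on the configured regular RT grid.
#' Configured interferent peaks are added to every run.
#'
#' @param config An [lcms_sim_config()].
#' @param amounts Data frame `lipid_name`, `adduct`, `mol` (mol injected).
#' @param sample_id Identifier stored with the run.
#' @return A [chrom_run()] (negative ion mode).
#' @export
simulate_lcms_run <- function(config, amounts, sample_id = "run") {
  stopifnot(inherits(config, "lcms_sim_config"),
            all(c("lipid_name", "adduct", "mol") %in% names(amounts)))
  rt <- seq(config$rt_range[1], config$rt_range[2], by = config$rt_step)
  blocks <- list()
  for (i in seq_len(nrow(amounts))) {
    if (amounts$mol[i] <= 0) next
    lip <- parse_lipid_name(amounts$lipid_name[i])
    cls <- lip$lipid_class
    if (!cls %in% names(config$class_rt)) {
      stop("no retention time configured for class ", cls, call. = FALSE)
    }
    mu <- config$class_rt[[cls]]
    area <- class_area_per_mol(config, cls) * amounts$mol[i] *
      lognormal_noise(1, config$noise_cv)
    mz <- adduct_mz(lip, amounts$adduct[i])$theoretical_mz
    sel <- which(abs(rt - mu) <= 5 * config$peak_sigma)
    if (!length(sel)) next
    blocks[[length(blocks) + 1L]] <- data.frame(
      rt = rt[sel], mz = mz,
      intensity = area * stats::dnorm(rt[sel], mu, config$peak_sigma)
    )
  }
  if (!is.null(config$interferents)) {
    for (i in seq_len(nrow(config$interferents))) {
      f <- config$interferents[i, ]
      sel <- which(abs(rt - f$rt) <= 5 * config$peak_sigma)
      if (!length(sel)) next
      blocks[[length(blocks) + 1L]] <- data.frame(
        rt = rt[sel], mz = f$mz,
        intensity = f$area * stats::dnorm(rt[sel], f$rt, config$peak_sigma)
      )
    }
  }
  points <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(rt = numeric(0), mz = numeric(0), intensity = numeric(0))
  chrom_run(points, rt_grid = rt, polarity = "-", sample_id = sample_id)
}

# amounts table (analyte + IS) for one vial of the calibration series;
# analyte_scale models a per-replicate preparation error (IS unaffected)
calibration_amounts <- function(config, panel, conc, analyte_scale = 1) {
  analyte <- data.frame(
    lipid_name = panel$lipid_name, adduct = panel$quant_adduct,
    mol = conc * config$extract_volume * analyte_scale,
    stringsAsFactors = FALSE
  )
  is_tab <- unique(data.frame(
    lipid_name = panel$is_name,
    adduct = panel$quant_adduct[match(panel$is_name, panel$is_name)],
    stringsAsFactors = FALSE
  ))
  is_tab$mol <- vapply(is_tab$lipid_name, function(nm) {
    cls <- parse_lipid_name(nm)$lipid_class
    config$is_amounts[[cls]]
  }, numeric(1))
  rbind(analyte, is_tab)
}

#' Simulate the internal-standard calibration dilution series
#'
#' One vial per calibration level containing every panel lipid at that
#' concentration in the extract volume, plus the constant IS spike (the
#' same 5 uL per vial); each vial is measured in three technical replicate
#' runs with independent noise. Optionally one level is corrupted by a
#' planted replicate-to-replicate analyte preparation error (lognormal
#' spread of the stated CV across the replicates, deterministic in shape so
#' the resulting area-ratio CV reliably exceeds it) so that downstream
#' level exclusion can be exercised; the corrupted level index is recorded
#' in attribute `corrupt_level`.
#'
#' @param config An [lcms_sim_config()].
#' @param panel Panel data frame (see [default_panel()]).
#' @param n_replicates Technical replicates per level (default 3).
#' @param corrupt_level Optional level index to corrupt.
#' @param corrupt_cv Replicate CV planted at the corrupted level.
#' @return List with one element per level: `conc` (mol/L) and `runs`
#'   (list of [chrom_run()]); attribute `corrupt_level`.
#' @export
simulate_calibration_series <- function(config, panel = default_panel(),
                                        n_replicates = 3L,
                                        corrupt_level = NULL,
                                        corrupt_cv = 0.5) {
  stopifnot(length(config$calibration_concentrations) >= 1L)
  set.seed(config$seed)
  # standardized replicate pattern for the planted preparation error
  z <- seq_len(n_replicates) - mean(seq_len(n_replicates))
  if (n_replicates > 1L) z <- z / stats::sd(z)
  levels <- lapply(seq_along(config$calibration_concentrations), function(l) {
    conc <- config$calibration_concentrations[l]
    corrupted <- !is.null(corrupt_level) && l == corrupt_level
    runs <- lapply(seq_len(n_replicates), function(r) {
      scale_r <- if (corrupted) exp(corrupt_cv * z[r]) else 1
      simulate_lcms_run(config,
                        calibration_amounts(config, panel, conc,
                                            analyte_scale = scale_r),
                        sample_id = sprintf("cal_L%02d_r%d", l, r))
    })
    list(conc = conc, runs = runs)
  })
  attr(levels, "corrupt_level") <- corrupt_level
  levels
}

#' A laser-microdissected tissue region
#'
#' @param region_label Region name matching the ground truth (`"WM"`,
#'   `"ML"`).
#' @param area Dissected surface area, mm^2.
#' @param thickness Section thickness, mm (default 0.020 = 20 um).
#' @param extraction_efficiency Fraction of lipid recovered (default 1).
#' @return Object of class `lmd_region`.
#' @export
lmd_region <- function(region_label, area, thickness = 0.020,
                       extraction_efficiency = 1.0) {
  stopifnot(area > 0, thickness > 0,
            extraction_efficiency > 0, extraction_efficiency <= 1)
  out <- list(region_label = region_label, area = area,
              thickness = thickness,
              extraction_efficiency = extraction_efficiency)
  class(out) <- "lmd_region"
  out
}

#' Lipid amounts in a dissected-region extract
#'
#' Converts the planted tissue concentration to mol in the extract:
#' `mol = conc (nmol/mm^3) * 1e-9 * area (mm^2) * thickness (mm) *
#' extraction_efficiency`.
#'
#' @param truth A [ground_truth()].
#' @param region An [lmd_region()].
#' @param panel Panel data frame.
#' @return Data frame `lipid_name`, `mol`.
#' @examples
#' gt <- default_ground_truth(c(20, 20))
#' simulate_lmd_extract(gt, lmd_region("WM", area = 1.0), default_panel())
#' @export
simulate_lmd_extract <- function(truth, region, panel = default_panel()) {
  stopifnot(inherits(region, "lmd_region"))
  if (!region$region_label %in% truth$concentrations$region) {
    stop("region '", region$region_label, "' not present in ground truth",
         call. = FALSE)
  }
  mol <- vapply(panel$lipid_name, function(nm) {
    truth_conc(truth, nm, region$region_label) * 1e-9 * region$area *
      region$thickness * region$extraction_efficiency
  }, numeric(1))
  data.frame(lipid_name = panel$lipid_name, mol = mol, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate LC-MS runs for dissected tissue regions
#'
#' Mirrors the wet-lab replicate structure: dissection and extraction are
#' performed independently on `n_sections` consecutive sections, and each
#' extract (spiked with the constant IS amounts) is measured in `n_tech`
#' technical replicate runs.
#'
#' @param config An [lcms_sim_config()].
#' @param truth A [ground_truth()].
#' @param region An [lmd_region()].
#' @param panel Panel data frame.
#' @param n_sections Section-level replicates (default 3).
#' @param n_tech Technical replicates per extract (default 3).
#' @param seed RNG seed for the run noise (default derived from the config
#'   seed, offset so it never replays the calibration-series stream).
#' @return List of sections, each a list of [chrom_run()]s.
#' @export
simulate_tissue_runs <- function(config, truth, region,
                                 panel = default_panel(),
                                 n_sections = 3L, n_tech = 3L,
                                 seed = NULL) {
  if (is.null(seed)) {
    # distinct stream per region, clear of the calibration-series stream
    seed <- config$seed + 10000L + sum(utf8ToInt(region$region_label))
  }
  set.seed(seed %% .Machine$integer.max)
  extract <- simulate_lmd_extract(truth, region, panel)
  amounts <- data.frame(lipid_name = panel$lipid_name,
                        adduct = panel$quant_adduct,
                        mol = extract$mol, stringsAsFactors = FALSE)
  is_tab <- calibration_amounts(config, panel, conc = 0)
  is_tab <- is_tab[is_tab$mol > 0, , drop = FALSE]
  amounts <- rbind(amounts, is_tab)
  lapply(seq_len(n_sections), function(s) {
    lapply(seq_len(n_tech), function(r) {
      simulate_lcms_run(config, amounts,
                        sample_id = sprintf("%s_s%d_r%d",
                                            region$region_label, s, r))
    })
  })
}
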