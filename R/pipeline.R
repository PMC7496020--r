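#' Map segmentation labels to planted regions
#'
#' For a synthetic demo run the dissectable regions must be named: each
#' k-means label is assigned to the ground-truth region (background, WM,
#' ML, ...) that the majority of its pixels fall in.
#'
#' @param map A [segment_msi()] result.
#' @param region_map Ground-truth integer region grid of the same shape.
#' @return Named integer vector: for each region code present in the truth,
#'   the segmentation label(s) assigned to it (majority vote), as a list.
#' @export
match_segments_to_regions <- function(map, region_map) {
  stopifnot(identical(dim(map$labels), dim(region_map)))
  lab <- as.vector(map$labels)
  reg <- as.vector(region_map)
  ok <- !is.na(lab)
  assign_of <- vapply(sort(unique(lab[ok])), function(l) {
    tt <- table(reg[ok & lab == l])
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  names(assign_of) <- sort(unique(lab[ok]))
  split(as.integer(names(assign_of)), assign_of)
}

#' Run the complete synthetic validation workflow
#'
#' The end-to-end demo: simulate ground-truthed MALDI and MALDI-2 MSI
#' datasets and the LC-MS experiment, segment the image, derive WM/ML
#' ROIs, compute summed-adduct ROI intensities, fit calibration curves,
#' quantify both dissected regions, normalize to tissue volume and combine
#' everything into the response-factor report. Every stage is a pure
#' function of (config, seed), so reruns are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created if needed.
#' @param truth Optional [ground_truth()]; defaults to the study-condition
#'   truth at the configured grid shape.
#' @param panel Panel data frame.
#' @return Invisibly, a list with `report`, `quant`, `rois`, `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir, truth = NULL,
                              panel = default_panel()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  if (is.null(truth)) {
    truth <- default_ground_truth(config$msi$grid_shape, seed = config$seed)
  }

  # --- imaging: both modalities, positive mode -----------------------------
  datasets <- list()
  for (modality in c("MALDI", "MALDI2")) {
    mc <- msi_sim_config(
      grid_shape = config$msi$grid_shape,
      pixel_size = config$msi$pixel_size,
      ppm_jitter_sd = config$msi$ppm_jitter_sd,
      multiplicative_noise_cv = config$msi$noise_cv,
      hotspot_fraction = config$msi$hotspot_fraction,
      hotspot_multiplier = config$msi$hotspot_multiplier,
      modality = modality, polarity = "+",
      seed = config$seed + if (modality == "MALDI") 0L else 1L
    )
    datasets[[modality]] <- simulate_msi(mc, truth, panel)
    write_imzml(datasets[[modality]],
                file.path(out_dir, sprintf("%s_pos.imzML", modality)))
  }

  # --- segmentation on the MALDI-2 image, ROI naming by truth overlap ------
  seg <- segment_msi(datasets$MALDI2, k = config$segmentation$k,
                     denoise = config$segmentation$denoise,
                     seed = config$segmentation$seed,
                     n_features = config$segmentation$n_features,
                     ppm_halfwidth = config$ppm_halfwidth)
  assignment <- match_segments_to_regions(seg, truth$region_map)
  region_names <- c("1" = "WM", "2" = "ML")
  rois <- list()
  for (code in names(assignment)) {
    if (!code %in% names(region_names)) next
    rois[[region_names[[code]]]] <- roi_from_segments(
      seg, assignment[[code]], region_names[[code]],
      pixel_size = config$msi$pixel_size)
  }
  if (!all(c("WM", "ML") %in% names(rois))) {
    stop("segmentation did not recover both WM and ML regions",
         call. = FALSE)
  }
  utils::write.csv(
    data.frame(label = as.vector(seg$labels),
               row = as.vector(row(seg$labels)) - 1L,
               col = as.vector(col(seg$labels)) - 1L),
    file.path(out_dir, "segmentation_labels.csv"), row.names = FALSE)

  # --- MSI-side summed ROI intensities -------------------------------------
  pos_lipids <- panel$lipid_name[panel$polarity %in% c("+", "both")]
  intens <- expand.grid(lipid_name = pos_lipids,
                        region = c("WM", "ML"),
                        modality = c("MALDI", "MALDI2"),
                        stringsAsFactors = FALSE)
  intens$polarity <- "+"
  intens$intensity <- mapply(function(lip, reg, mod) {
    summed_adduct_intensity(datasets[[mod]], lip,
                            config$adducts$positive, rois[[reg]],
                            ppm_halfwidth = config$ppm_halfwidth)
  }, intens$lipid_name, intens$region, intens$modality)

  # --- LC-MS: calibration + dissected-region quantification ----------------
  lc <- lcms_sim_config(noise_cv = config$lcms$noise_cv,
                        extract_volume = config$extract_volume_L,
                        seed = config$seed)
  series <- simulate_calibration_series(lc, panel)
  curves <- fit_panel_calibrations(series, panel,
                                   cv_threshold = config$cv_threshold,
                                   ppm_halfwidth = config$ppm_halfwidth)
  quant <- list()
  for (reg in c("WM", "ML")) {
    region <- lmd_region(reg, area = rois[[reg]]$area,
                         thickness = config$thickness_mm)
    runs <- simulate_tissue_runs(lc, truth, region, panel)
    quant[[reg]] <- quantify_panel(runs, curves, panel, region,
                                   extract_volume = config$extract_volume_L,
                                   ppm_halfwidth = config$ppm_halfwidth)
  }
  quant_all <- do.call(rbind, quant)
  rownames(quant_all) <- NULL
  utils::write.csv(format(quant_all, digits = 10),
                   file.path(out_dir, "quantification.csv"),
                   row.names = FALSE)

  # --- response factors ----------------------------------------------------
  report <- build_report(quant_all, intens,
                         path = file.path(out_dir, "response_report.csv"))

  manifest <- list(
    tool = "msiresponse",
    version = as.character(utils::packageVersion("msiresponse")),
    config_hash = config_hash(config),
    seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = c("MALDI_pos.imzML", "MALDI2_pos.imzML",
                "segmentation_labels.csv", "quantification.csv",
                "response_report.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, quant = quant_all, rois = rois,
                 manifest = manifest, segmentation = seg, truth = truth))
}

#' Fit calibration curves for every panel lipid from a simulated series
#'
#' Integrates analyte and IS peaks in every replicate run of every level
#' and fits one [fit_calibration()] curve per lipid.
#'
#' @param series Output of [simulate_calibration_series()] (or any list of
#'   `list(conc=, runs=)` records).
#' @param panel Panel data frame.
#' @param cv_threshold Passed to [fit_calibration()].
#' @param ppm_halfwidth XIC window half-width, ppm.
#' @param weights Calibration weighting; the panel default is `"1/x"`
#'   because the dilution series spans three decades while sample extracts
#'   sit near its low end — under unweighted OLS the intercept inherits the
#'   absolute noise of the top levels and corrupts low-end
#'   back-calculation.
#' @return Named list of `calibration_curve`s, keyed by lipid name.
#' @export
fit_panel_calibrations <- function(series, panel = default_panel(),
                                   cv_threshold = 0.2, ppm_halfwidth = 5,
                                   weights = c("1/x", "none")) {
  weights <- match.arg(weights)
  curves <- list()
  for (i in seq_len(nrow(panel))) {
    lip <- panel$lipid_name[i]
    ion <- adduct_mz(lip, panel$quant_adduct[i])
    is_ion <- adduct_mz(panel$is_name[i], panel$quant_adduct[i])
    ratios <- lapply(series, function(level) {
      vapply(level$runs, function(run) {
        ra <- peak_area(run, ion, ppm_halfwidth)
        ri <- peak_area(run, is_ion, ppm_halfwidth)
        if (ri <= 0) stop("IS peak missing in calibration run '",
                          run$sample_id, "'", call. = FALSE)
        ra / ri
      }, numeric(1))
    })
    conc <- vapply(series, `[[`, numeric(1), "conc")
    curves[[lip]] <- fit_calibration(ratios, conc,
                                     cv_threshold = cv_threshold,
                                     weights = weights, lipid = lip)
  }
  curves
}

# area of the largest detected peak of an ion in a run (0 when absent)
peak_area <- function(run, ion, ppm_halfwidth = 5) {
  p <- detect_peaks(extract_xic(run, ion, ppm_halfwidth))
  if (nrow(p) == 0L) 0 else p$area[1]
}
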