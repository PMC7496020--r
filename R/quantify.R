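#' Quantify one lipid in one LC-MS run
#'
#' Extracts analyte and internal-standard ion chromatograms, takes the
#' largest detected peak of each, and back-calculates the extract
#' concentration from the area ratio through the calibration curve.
#'
#' @param run A [chrom_run()].
#' @param curve A [fit_calibration()] result.
#' @param ion Analyte `ion_species` (from [adduct_mz()]).
#' @param is_ion Internal-standard `ion_species`.
#' @param ppm_halfwidth XIC window half-width, ppm.
#' @return Extract concentration, mol/L.
#' @export
quantify_extract <- function(run, curve, ion, is_ion, ppm_halfwidth = 5) {
  xa <- extract_xic(run, ion, ppm_halfwidth)
  xi <- extract_xic(run, is_ion, ppm_halfwidth)
  pa <- detect_peaks(xa)
  pi_ <- detect_peaks(xi)
  if (nrow(pi_) == 0L) {
    stop("internal-standard peak not found for m/z ",
         sprintf("%.4f", xi$mz), " in run '", run$sample_id,
         "' (failed spike or extraction)", call. = FALSE)
  }
  if (nrow(pa) == 0L) return(0)
  ratio <- pa$area[1] / pi_$area[1]
  predict(curve, area_ratio = ratio)
}

#' Convert an extract concentration to tissue molar concentration
#'
#' `amount (nmol) = extract_conc (mol/L) * extract_volume (L) * 1e9`;
#' `tissue volume (mm^3) = area (mm^2) * thickness (mm)`; concentration is
#' their ratio in nmol/mm^3, the unit used for fresh frozen tissue.
#'
#' @param extract_conc Extract concentration, mol/L.
#' @param area Dissected surface area, mm^2.
#' @param extract_volume Extract volume, L (default 20e-6 = 20 uL).
#' @param thickness Section thickness, mm (default 0.020 = 20 um).
#' @param lipid,region Optional identifiers carried in the result.
#' @param sd Optional standard deviation across section replicates,
#'   nmol/mm^3.
#' @return Object of class `quant_result` with `amount` (nmol),
#'   `tissue_volume` (mm^3) and `tissue_concentration` (nmol/mm^3).
#' @examples
#' tissue_concentration(5e-6, area = 2.5)   # 0.1 nmol / 0.05 mm^3 = 2
#' @export
tissue_concentration <- function(extract_conc, area,
                                 extract_volume = 20e-6, thickness = 0.020,
                                 lipid = NULL, region = NULL, sd = NA_real_) {
  stopifnot(extract_conc >= 0, area > 0, extract_volume > 0, thickness > 0)
  amount <- extract_conc * extract_volume * 1e9
  volume <- area * thickness
  out <- list(lipid = lipid, region = region,
              extract_concentration = extract_conc,
              amount = amount, tissue_volume = volume,
              tissue_concentration = amount / volume, sd = sd)
  class(out) <- "quant_result"
  out
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> %s %s: %.4g nmol in %.4g mm^3 = %.4g nmol/mm^3%s\n",
    if (is.null(x$lipid)) "" else x$lipid,
    if (is.null(x$region)) "" else paste0("(", x$region, ")"),
    x$amount, x$tissue_volume, x$tissue_concentration,
    if (is.na(x$sd)) "" else sprintf(" (SD %.3g)", x$sd)))
  invisible(x)
}

#' Quantify a panel across replicate tissue runs
#'
#' Applies [quantify_extract()] to every technical replicate of every
#' section extract, averages technical replicates within a section, and
#' reports the mean and SD of tissue concentration across sections
#' (technical replicates are averaged first, so the SD reflects the
#' independent dissection/extraction replicates).
#'
#' @param runs Nested list as from [simulate_tissue_runs()]: sections, each
#'   a list of [chrom_run()]s.
#' @param curves Named list of [fit_calibration()] objects, one per panel
#'   lipid name.
#' @param panel Panel data frame (see [default_panel()]).
#' @param region An [lmd_region()] giving the dissected geometry.
#' @param extract_volume Extract volume, L.
#' @param ppm_halfwidth XIC window half-width, ppm.
#' @return Data frame with one row per lipid: `lipid_name`, `region`,
#'   `extract_concentration` (mol/L, mean), `amount` (nmol),
#'   `tissue_concentration` (nmol/mm^3), `sd` (across sections).
#' @export
quantify_panel <- function(runs, curves, panel, region,
                           extract_volume = 20e-6, ppm_halfwidth = 5) {
  stopifnot(inherits(region, "lmd_region"))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    lip <- panel$lipid_name[i]
    ion <- adduct_mz(lip, panel$quant_adduct[i])
    is_ion <- adduct_mz(panel$is_name[i], panel$quant_adduct[i])
    curve <- curves[[lip]]
    if (is.null(curve)) stop("no calibration curve for ", lip,
                             call. = FALSE)
    section_conc <- vapply(runs, function(section) {
      mean(vapply(section, function(run) {
        quantify_extract(run, curve, ion, is_ion, ppm_halfwidth)
      }, numeric(1)))
    }, numeric(1))
    per_section <- vapply(section_conc, function(cc) {
      tissue_concentration(cc, area = region$area,
                           extract_volume = extract_volume,
                           thickness = region$thickness)$tissue_concentration
    }, numeric(1))
    qr <- tissue_concentration(mean(section_conc), area = region$area,
                               extract_volume = extract_volume,
                               thickness = region$thickness,
                               lipid = lip, region = region$region_label,
                               sd = stats::sd(per_section))
    data.frame(lipid_name = lip, region = region$region_label,
               extract_concentration = qr$extract_concentration,
               amount = qr$amount,
               tissue_concentration = qr$tissue_concentration,
               sd = qr$sd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen a target ion for isobaric interference
#'
#' In the target's XIC (ppm-tolerant window), every detected peak whose
#' apex lies outside the expected retention window is an interferent; its
#' contribution is its area relative to the main peak's. The screen passes
#' ("clean") when every contribution is at or below the threshold — by
#' default 5%, the conventional cut for calling an interference sizeable.
#'
#' @param run A [chrom_run()].
#' @param ion Target `ion_species` or m/z.
#' @param main_rt_window `c(lo, hi)` retention window (min) of the genuine
#'   peak.
#' @param ppm_halfwidth XIC window half-width, ppm.
#' @param contribution_threshold Maximal tolerated area fraction.
#' @return List of class `interference_report`: `clean` (logical),
#'   `main_peak` (one-row data frame), `interferents` (data frame with
#'   `contribution` column).
#' @export
interference_check <- function(run, ion, main_rt_window, ppm_halfwidth = 5,
                               contribution_threshold = 0.05) {
  stopifnot(length(main_rt_window) == 2L,
            main_rt_window[1] < main_rt_window[2])
  x <- extract_xic(run, ion, ppm_halfwidth)
  peaks <- detect_peaks(x)
  in_win <- peaks$apex_rt >= main_rt_window[1] &
    peaks$apex_rt <= main_rt_window[2]
  if (!any(in_win)) {
    stop("no main peak found inside the retention window [",
         main_rt_window[1], ", ", main_rt_window[2], "] min", call. = FALSE)
  }
  main <- peaks[in_win, , drop = FALSE][1, , drop = FALSE]
  inter <- peaks[!in_win, , drop = FALSE]
  inter$contribution <- if (nrow(inter)) inter$area / main$area else numeric(0)
  out <- list(clean = all(inter$contribution <= contribution_threshold),
              main_peak = main, interferents = inter,
              threshold = contribution_threshold)
  class(out) <- "interference_report"
  out
}

#' @export
print.interference_report <- function(x, ...) {
  cat(sprintf("<interference_report> %s: main peak at %.2f min, %d interferent(s)\n",
              if (x$clean) "clean" else "FLAGGED", x$main_peak$apex_rt,
              nrow(x$interferents)))
  if (nrow(x$interferents)) {
    cat(sprintf("  apex %.2f min, contribution %.1f%%\n",
                x$interferents$apex_rt, 100 * x$interferents$contribution),
        sep = "")
  }
  invisible(x)
}
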