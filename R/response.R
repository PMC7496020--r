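#' Signal response factor: intensity per mol
#'
#' The central comparison statistic: the mean summed MSI signal intensity
#' of a lipid's accessible ion species in a region, divided by the region's
#' molar concentration as established by quantitative LC-MS. Tissue- and
#' modality-specific differences in this value quantify ion suppression
#' bias that raw ion images cannot reveal.
#'
#' @param intensity Summed mean ROI intensity (see
#'   [summed_adduct_intensity()]).
#' @param concentration Tissue concentration, nmol/mm^3; must be positive
#'   for a defined factor.
#' @param lipid,region,modality,polarity Optional identifiers.
#' @return Object of class `response_factor`: `value` (intensity per
#'   nmol/mm^3, `NA` when undefined), `defined`, and the inputs.
#' @examples
#' response_factor(500, 2)$value   # 250
#' @export
response_factor <- function(intensity, concentration, lipid = NULL,
                            region = NULL, modality = NULL,
                            polarity = NULL) {
  defined <- is.finite(concentration) && concentration > 0 &&
    is.finite(intensity) && intensity >= 0
  out <- list(
    lipid = lipid, region = region, modality = modality,
    polarity = polarity,
    intensity = intensity, concentration = concentration,
    value = if (defined) intensity / concentration else NA_real_,
    defined = defined
  )
  class(out) <- "response_factor"
  out
}

#' @export
print.response_factor <- function(x, ...) {
  cat(sprintf("<response_factor> %s%s: %s\n",
              if (is.null(x$lipid)) "" else paste0(x$lipid, " "),
              paste(c(x$region, x$modality, x$polarity), collapse = "/"),
              if (x$defined) sprintf("%.4g per (nmol/mm^3)", x$value)
              else "undefined (non-positive concentration)"))
  invisible(x)
}

rf_value <- function(rf) {
  if (inherits(rf, "response_factor")) {
    if (!rf$defined) return(NA_real_)
    rf$value
  } else {
    as.numeric(rf)
  }
}

#' Region bias of the response: ML over WM
#'
#' @param rf_ml,rf_wm [response_factor()]s (or bare values) for the
#'   molecular-layer-like and white-matter-like region.
#' @return `rf_ml / rf_wm`; values above 1 indicate an ML-biased response.
#'   `NA` when either input is undefined.
#' @export
bias_ratio <- function(rf_ml, rf_wm) {
  a <- rf_value(rf_ml); b <- rf_value(rf_wm)
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (b <= 0) return(NA_real_)
  a / b
}

#' Postionization gain of the response: MALDI-2 over MALDI
#'
#' @param rf_maldi2,rf_maldi [response_factor()]s (or bare values) for the
#'   same lipid/region under the two modalities.
#' @return `rf_maldi2 / rf_maldi`; `NA` when either input is undefined.
#' @export
modality_gain <- function(rf_maldi2, rf_maldi) {
  a <- rf_value(rf_maldi2); b <- rf_value(rf_maldi)
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (b <= 0) return(NA_real_)
  a / b
}

#' Combine ROI intensities and concentrations into a response report
#'
#' Joins the MSI-side summed ROI intensities with the LC-MS tissue
#' concentrations into one row per lipid x region x modality x polarity,
#' computes the response factor for each row and the ML/WM bias ratio and
#' MALDI-2/MALDI gain where both sides exist. Pairings present on one side
#' only are listed in the `gaps` section rather than silently dropped.
#'
#' @param quant_results Data frame from [quantify_panel()] (columns
#'   `lipid_name`, `region`, `tissue_concentration`), possibly row-bound
#'   over regions.
#' @param roi_intensities Data frame with columns `lipid_name`, `region`,
#'   `modality`, `polarity`, `intensity` (summed ROI means).
#' @param path Optional CSV path to write the table to.
#' @return Object of class `response_report`: `table` (one row per
#'   combination with `response`, `bias_ratio`, `modality_gain`) and `gaps`
#'   (character vector of unmatched keys).
#' @export
build_report <- function(quant_results, roi_intensities, path = NULL) {
  need <- c("lipid_name", "region", "modality", "polarity", "intensity")
  stopifnot(all(need %in% names(roi_intensities)))
  qkey <- paste(quant_results$lipid_name, quant_results$region)
  tab <- roi_intensities
  m <- match(paste(tab$lipid_name, tab$region), qkey)
  tab$concentration <- quant_results$tissue_concentration[m]
  gaps <- character(0)
  if (anyNA(m)) {
    gaps <- c(gaps, sprintf("no concentration for %s in %s",
                            tab$lipid_name[is.na(m)], tab$region[is.na(m)]))
  }
  unmatched_q <- setdiff(qkey, paste(tab$lipid_name, tab$region))
  if (length(unmatched_q)) {
    gaps <- c(gaps, sprintf("no ROI intensity for %s", unmatched_q))
  }
  tab$response <- ifelse(
    !is.na(tab$concentration) & tab$concentration > 0,
    tab$intensity / tab$concentration, NA_real_)

  key_of <- function(l, m_, p) paste(l, m_, p)
  resp_at <- function(l, r, m_, p) {
    i <- which(tab$lipid_name == l & tab$region == r & tab$modality == m_ &
                 tab$polarity == p)
    if (!length(i)) NA_real_ else tab$response[i[1]]
  }
  tab$bias_ratio <- mapply(function(l, m_, p) {
    ml <- resp_at(l, "ML", m_, p); wm <- resp_at(l, "WM", m_, p)
    if (is.na(ml) || is.na(wm) || wm <= 0) NA_real_ else ml / wm
  }, tab$lipid_name, tab$modality, tab$polarity)
  tab$modality_gain <- mapply(function(l, r, p) {
    m2 <- resp_at(l, r, "MALDI2", p); m1 <- resp_at(l, r, "MALDI", p)
    if (is.na(m2) || is.na(m1) || m1 <= 0) NA_real_ else m2 / m1
  }, tab$lipid_name, tab$region, tab$polarity)

  ord <- order(tab$polarity, tab$lipid_name, tab$modality, tab$region)
  tab <- tab[ord, c("lipid_name", "region", "modality", "polarity",
                    "intensity", "concentration", "response",
                    "bias_ratio", "modality_gain")]
  rownames(tab) <- NULL
  out <- list(table = tab, gaps = gaps)
  class(out) <- "response_report"
  if (!is.null(path)) write_report_csv(out, path)
  out
}

#' @export
print.response_report <- function(x, ...) {
  cat("<response_report> ", nrow(x$table), " rows\n", sep = "")
  print(x$table, digits = 4)
  if (length(x$gaps)) {
    cat("Gaps:\n"); cat(paste0("  - ", x$gaps, "\n"), sep = "")
  }
  invisible(x)
}

#' @rdname build_report
#' @param report A `response_report`.
#' @export
write_report_csv <- function(report, path) {
  tab <- report$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) {
    ifelse(is.na(v), "", format(v, digits = 10, trim = TRUE,
                                scientific = TRUE))
  })
  con <- file(path, "w")
  on.exit(close(con))
  if (length(report$gaps)) {
    writeLines(paste0("# gap: ", report$gaps), con)
  }
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname build_report
#' @export
read_report_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  hdr <- grep("^# gap: ", readLines(path), value = TRUE)
  out <- list(table = tab, gaps = sub("^# gap: ", "", hdr))
  class(out) <- "response_report"
  out
}

#' Bar plot of response factors by lipid, region and modality
#'
#' @param x A `response_report`.
#' @param polarity Which polarity to display.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.response_report <- function(x, polarity = "+", ...) {
  tab <- x$table[x$table$polarity == polarity & !is.na(x$table$response), ]
  if (!nrow(tab)) {
    stop("nothing to plot for polarity ", polarity, call. = FALSE)
  }
  lip <- unique(tab$lipid_name)
  groups <- unique(paste(tab$modality, tab$region))
  m <- matrix(NA_real_, length(groups), length(lip),
              dimnames = list(groups, lip))
  for (i in seq_len(nrow(tab))) {
    m[paste(tab$modality[i], tab$region[i]), tab$lipid_name[i]] <-
      tab$response[i]
  }
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "signal intensity per (nmol/mm^3)",
                    las = 2, ...)
  invisible(x)
}
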