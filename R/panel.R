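#' The default six-lipid target panel
#'
#' The cerebellum panel: PG(34:1), PE(34:1), PC(34:1), PC(38:4), PC(40:6)
#' imaged in positive mode as protonated, sodiated and potassiated species,
#' and PG(34:1), PE(34:1) and the sulfatide SHexCer(d18:1/24:1) in negative
#' mode as deprotonated species. For LC-MS quantification (negative mode)
#' PC species are measured as the acetate adduct; each class has a
#' deuterated internal standard.
#'
#' @return Data frame with columns `lipid_name`, `adducts` (semicolon list),
#'   `polarity`, `quant_adduct` (adduct used for LC-MS quantification) and
#'   `is_name` (internal-standard lipid name for the class).
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  data.frame(
    lipid_name = c("PG(34:1)", "PE(34:1)", "PC(34:1)", "PC(38:4)",
                   "PC(40:6)", "SHexCer(d18:1/24:1)"),
    adducts = c("[M+H]+;[M+Na]+;[M+K]+;[M-H]-",
                "[M+H]+;[M+Na]+;[M+K]+;[M-H]-",
                "[M+H]+;[M+Na]+;[M+K]+",
                "[M+H]+;[M+Na]+;[M+K]+",
                "[M+H]+;[M+Na]+;[M+K]+",
                "[M-H]-"),
    polarity = c("both", "both", "+", "+", "+", "-"),
    quant_adduct = c("[M-H]-", "[M-H]-", "[M+OAc]-", "[M+OAc]-",
                     "[M+OAc]-", "[M-H]-"),
    is_name = c("PG(15:0/18:1)-d7", "PE(15:0/18:1)-d7", "PC(15:0/18:1)-d7",
                "PC(15:0/18:1)-d7", "PC(15:0/18:1)-d7",
                "SHexCer(d18:1/18:0)-d3"),
    stringsAsFactors = FALSE
  )
}

#' Read a target panel from CSV
#'
#' The file must have columns `lipid_name`, `adducts` (semicolon-separated
#' adduct names) and `polarity`; extra columns are carried through. Every
#' lipid name is validated by [parse_lipid_name()].
#'
#' @param path CSV file path.
#' @return Panel data frame as in [default_panel()].
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lipid_name", "adducts", "polarity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(lapply(df$lipid_name, parse_lipid_name))
  df
}

#' Expand a panel into ion species for one polarity
#'
#' @param panel Panel data frame ([default_panel()] layout).
#' @param polarity `"+"` or `"-"`.
#' @param table A [mass_table()].
#' @return Data frame with columns `lipid_name`, `adduct`, `mz`.
#' @examples
#' panel_ions(default_panel(), "+")
#' @export
panel_ions <- function(panel, polarity, table = mass_table()) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    adds <- strsplit(panel$adducts[i], ";", fixed = TRUE)[[1]]
    adds <- trimws(adds)
    keep <- vapply(adds, function(a) adduct_by_name(a, table)$polarity,
                   character(1)) == polarity
    adds <- adds[keep]
    if (!length(adds)) return(NULL)
    mzs <- vapply(adds, function(a) {
      adduct_mz(panel$lipid_name[i], a, table)$theoretical_mz
    }, numeric(1))
    data.frame(lipid_name = panel$lipid_name[i], adduct = adds, mz = mzs,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
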