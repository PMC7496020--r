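#' Construct a ground-truth object for simulation
#'
#' Bundles everything the synthetic generators need to plant and later
#' recover: a region label grid, region-specific molar concentrations,
#' region- and modality-specific signal response factors, and the fractions
#' in which each lipid's signal is split across its adduct species.
#'
#' @param region_map Integer matrix; 0 = background, 1 = white-matter-like
#'   (WM), 2 = molecular-layer-like (ML). Further positive labels allowed.
#' @param concentrations Data frame `lipid_name`, `region`, `conc`
#'   (nmol/mm^3).
#' @param response_factors Data frame `lipid_name`, `region`, `modality`
#'   (`"MALDI"`/`"MALDI2"`), `polarity`, `rf` (intensity per nmol/mm^3).
#' @param adduct_fractions Data frame `lipid_name`, `adduct`, `fraction`;
#'   fractions must sum to 1 per lipid and polarity.
#' @param seed Integer seed recorded with the truth.
#' @return Object of class `ground_truth`.
#' @seealso [default_ground_truth()]
#' @export
ground_truth <- function(region_map, concentrations, response_factors,
                         adduct_fractions, seed = 1L) {
  stopifnot(is.matrix(region_map),
            all(region_map >= 0),
            all(concentrations$conc >= 0),
            all(response_factors$rf >= 0))
  tab <- adduct_table()
  pol <- tab$polarity[match(adduct_fractions$adduct, tab$name)]
  if (anyNA(pol)) stop("unknown adduct in adduct_fractions", call. = FALSE)
  sums <- tapply(adduct_fractions$fraction,
                 paste(adduct_fractions$lipid_name, pol), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("adduct fractions must sum to 1 per lipid and polarity",
         call. = FALSE)
  }
  out <- list(region_map = region_map, concentrations = concentrations,
              response_factors = response_factors,
              adduct_fractions = adduct_fractions, seed = as.integer(seed))
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  tabulation <- table(x$region_map)
  cat("<ground_truth> ", nrow(x$region_map), "x", ncol(x$region_map),
      " grid; region pixel counts: ",
      paste(names(tabulation), tabulation, sep = "=", collapse = ", "),
      "\n  ", length(unique(x$concentrations$lipid_name)), " lipids, ",
      nrow(x$response_factors), " response factors\n", sep = "")
  invisible(x)
}

# Deterministic two-region cerebellum-like geometry: a lobed central blob of
# white matter surrounded by molecular layer, inside a background margin.
two_region_map <- function(nrow_px, ncol_px) {
  m <- matrix(0L, nrow_px, ncol_px)
  rc <- (nrow_px + 1) / 2
  cc <- (ncol_px + 1) / 2
  r <- row(m); ci <- col(m)
  # tissue: central ellipse covering ~80% of each dimension
  tissue <- ((r - rc) / (0.42 * nrow_px))^2 +
    ((ci - cc) / (0.42 * ncol_px))^2 <= 1
  m[tissue] <- 2L
  # white matter: smaller lobed core (angular modulation mimics arborization)
  ang <- atan2(r - rc, ci - cc)
  rad <- sqrt(((r - rc) / nrow_px)^2 + ((ci - cc) / ncol_px)^2)
  core <- rad <= 0.18 * (1 + 0.35 * cos(5 * ang))
  m[tissue & core] <- 1L
  m
}

#' Default planted truth mirroring the murine cerebellum study conditions
#'
#' Concentrations are the measured white-matter and molecular-layer values
#' for the six-lipid panel (nmol/mm^3): sulfatide 10.2/0.37, PG(34:1)
#' 0.41/0.43, PE(34:1) 1.46/0.46, PC(34:1) 9.07/7.00, PC(38:4) 1.17/1.20,
#' PC(40:6) 1.25/2.14. Response factors are planted to reproduce the
#' observed phenomenology: an ML-biased response for every
#' glycerophospholipid, stronger under MALDI-2; a MALDI-2 gain for PE and PG
#' in both regions and for PC only on the ML; and a slightly WM-biased
#' sulfatide response in negative mode that decreases under MALDI-2.
#'
#' @param shape `c(rows, cols)` of the region grid.
#' @param seed Seed recorded with the truth.
#' @return A [ground_truth()] object.
#' @examples
#' gt <- default_ground_truth(c(60, 60))
#' table(gt$region_map)
#' @export
default_ground_truth <- function(shape = c(100L, 100L), seed = 1L) {
  conc <- data.frame(
    lipid_name = rep(c("SHexCer(d18:1/24:1)", "PG(34:1)", "PE(34:1)",
                       "PC(34:1)", "PC(38:4)", "PC(40:6)"), each = 2L),
    region = rep(c("WM", "ML"), times = 6L),
    conc = c(10.2, 0.37, 0.41, 0.43, 1.46, 0.46,
             9.07, 7.00, 1.17, 1.20, 1.25, 2.14),
    stringsAsFactors = FALSE
  )

  rf_row <- function(lipid, pol, wm1, ml1, wm2, ml2) {
    data.frame(
      lipid_name = lipid,
      region = c("WM", "ML", "WM", "ML"),
      modality = c("MALDI", "MALDI", "MALDI2", "MALDI2"),
      polarity = pol,
      rf = c(wm1, ml1, wm2, ml2),
      stringsAsFactors = FALSE
    )
  }
  rf <- rbind(
    # positive mode: ML bias throughout, MALDI-2 gain for PE/PG everywhere,
    # for PC only on the ML
    rf_row("PG(34:1)", "+",    50,  250,  400,  3000),
    rf_row("PE(34:1)", "+",    80,  400,  800,  6000),
    rf_row("PC(34:1)", "+",  2000, 6000, 2000, 12000),
    rf_row("PC(38:4)", "+",  1800, 5400, 1800, 10800),
    rf_row("PC(40:6)", "+",  1500, 5000, 1500, 10000),
    # negative mode: deprotonated species only
    rf_row("PG(34:1)", "-",    60,  300,  500,  2500),
    rf_row("PE(34:1)", "-",    90,  450,  700,  3500),
    rf_row("SHexCer(d18:1/24:1)", "-", 1200, 1000, 600, 500)
  )

  pos_lip <- c("PG(34:1)", "PE(34:1)", "PC(34:1)", "PC(38:4)", "PC(40:6)")
  neg_lip <- c("PG(34:1)", "PE(34:1)", "SHexCer(d18:1/24:1)")
  frac <- rbind(
    data.frame(lipid_name = rep(pos_lip, each = 3L),
               adduct = rep(c("[M+H]+", "[M+Na]+", "[M+K]+"), times = 5L),
               fraction = rep(c(0.35, 0.40, 0.25), times = 5L),
               stringsAsFactors = FALSE),
    data.frame(lipid_name = neg_lip, adduct = "[M-H]-", fraction = 1,
               stringsAsFactors = FALSE)
  )

  ground_truth(two_region_map(shape[1], shape[2]), conc, rf, frac,
               seed = seed)
}

# lookup helpers ------------------------------------------------------------

truth_conc <- function(truth, lipid, region) {
  i <- which(truth$concentrations$lipid_name == lipid &
               truth$concentrations$region == region)
  if (!length(i)) stop("no planted concentration for ", lipid, " in ",
                       region, call. = FALSE)
  truth$concentrations$conc[i[1]]
}

truth_rf <- function(truth, lipid, region, modality, polarity) {
  d <- truth$response_factors
  i <- which(d$lipid_name == lipid & d$region == region &
               d$modality == modality & d$polarity == polarity)
  if (!length(i)) stop("no planted response factor for ", lipid, " (",
                       region, ", ", modality, ", ", polarity, ")",
                       call. = FALSE)
  d$rf[i[1]]
}
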