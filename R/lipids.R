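#' Parse a lipid shorthand name
#'
#' Parses sum-composition shorthand such as `"PC(34:1)"`, chain-resolved
#' shorthand such as `"PE(16:0/18:1)"`, and sulfatide nomenclature
#' `"SHexCer(d18:1/24:1)"` or its long spelling
#' `"(3'-sulfo)Galb1-1Cer(d18:1/24:1)"` (unicode prime and beta accepted).
#' A trailing `-d<k>` marks a deuterium-labeled internal standard with `k`
#' heavy hydrogens, e.g. `"PC(15:0/18:1)-d7"`.
#'
#' Lipids are treated at sum-composition level: the class, the total number
#' of acyl carbons and the total number of C-C double bonds. For sulfatides
#' the sphingoid base (default d18:1) is tracked separately from the N-acyl
#' chain; totals include both.
#'
#' @param text Lipid name.
#' @return An object of class `lipid_species`: list with `lipid_class`
#'   (`"PC"`, `"PE"`, `"PG"` or `"SHexCer"`), `total_acyl_carbons`,
#'   `total_double_bonds`, `chains` (two-column matrix or `NULL`),
#'   `sphingoid` (length-2 vector for SHexCer, else `NULL`),
#'   `label_extra_neutrons` and the canonical `name`.
#' @examples
#' parse_lipid_name("PC(34:1)")
#' parse_lipid_name("PE(16:0/18:1)")
#' parse_lipid_name("SHexCer(d18:1/24:1)")
#' @export
parse_lipid_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)
  label <- 0L
  m <- regmatches(raw, regexec("-d([0-9]+)$", raw))[[1]]
  if (length(m)) {
    label <- as.integer(m[2])
    raw <- sub("-d[0-9]+$", "", raw)
  }
  # long sulfatide spelling -> canonical SHexCer
  sulfo <- "^\\(3['′]-sulfo\\)Gal(b|β)1-1Cer"
  if (grepl(sulfo, raw)) raw <- sub(sulfo, "SHexCer", raw)

  m <- regmatches(raw, regexec("^([A-Za-z]+)\\(([^)]*)\\)$", raw))[[1]]
  if (!length(m)) stop("malformed lipid name: '", text, "'", call. = FALSE)
  cls <- m[2]
  body <- m[3]
  if (!cls %in% c("PC", "PE", "PG", "SHexCer")) {
    stop("unknown lipid class '", cls, "' in '", text, "'", call. = FALSE)
  }

  parse_cd <- function(tok, what) {
    p <- regmatches(tok, regexec("^([0-9]+):([0-9]+)$", tok))[[1]]
    if (!length(p)) {
      stop("malformed ", what, " token '", tok, "' in '", text, "'",
           call. = FALSE)
    }
    c(as.integer(p[2]), as.integer(p[3]))
  }

  toks <- strsplit(body, "/", fixed = TRUE)[[1]]
  sphingoid <- NULL
  chains <- NULL
  if (cls == "SHexCer") {
    if (length(toks) != 2L || !grepl("^d", toks[1])) {
      stop("sulfatide requires d-sphingoid form 'SHexCer(dC:D/C:D)', got '",
           text, "'", call. = FALSE)
    }
    sphingoid <- parse_cd(sub("^d", "", toks[1]), "sphingoid")
    acyl <- parse_cd(toks[2], "N-acyl")
    chains <- rbind(acyl)
    carbons <- sphingoid[1] + acyl[1]
    dbs <- sphingoid[2] + acyl[2]
  } else if (length(toks) == 1L) {
    cd <- parse_cd(toks[1], "composition")
    carbons <- cd[1]
    dbs <- cd[2]
  } else if (length(toks) == 2L) {
    ch1 <- parse_cd(toks[1], "sn-1 chain")
    ch2 <- parse_cd(toks[2], "sn-2 chain")
    chains <- rbind(ch1, ch2)
    carbons <- ch1[1] + ch2[1]
    dbs <- ch1[2] + ch2[2]
  } else {
    stop("expected one or two acyl chains in '", text, "'", call. = FALSE)
  }
  if (carbons < 2L) stop("need at least 2 acyl carbons in '", text, "'",
                         call. = FALSE)
  if (dbs > carbons) {
    stop("double bonds (", dbs, ") exceed carbons (", carbons, ") in '",
         text, "'", call. = FALSE)
  }
  if (!is.null(chains)) rownames(chains) <- NULL

  out <- list(
    lipid_class = cls,
    total_acyl_carbons = carbons,
    total_double_bonds = dbs,
    chains = chains,
    sphingoid = sphingoid,
    label_extra_neutrons = label,
    name = canonical_lipid_name(cls, carbons, dbs, chains, sphingoid, label)
  )
  class(out) <- "lipid_species"
  out
}

canonical_lipid_name <- function(cls, carbons, dbs, chains, sphingoid, label) {
  body <- if (cls == "SHexCer") {
    sprintf("d%d:%d/%d:%d", sphingoid[1], sphingoid[2],
            chains[1, 1], chains[1, 2])
  } else {
    sprintf("%d:%d", carbons, dbs)
  }
  nm <- sprintf("%s(%s)", cls, body)
  if (label > 0L) nm <- sprintf("%s-d%d", nm, label)
  nm
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", x$name, "\n", sep = "")
  invisible(x)
}

#' Build the molecular formula of a lipid
#'
#' Class compositions are standard diacyl glycerophospholipid and d-series
#' sulfatide chemistry: for total composition C:D,
#' PC gives C(C+8) H(2C-2D+16) N O8 P, PE gives C(C+5) H(2C-2D+10) N O8 P,
#' PG gives C(C+6) H(2C-2D+11) O10 P, and SHexCer(d18:1/N:n) gives
#' C(24+N) H(45+2N-2n) N O11 S. A deuterium label converts
#' `label_extra_neutrons` hydrogens to deuterium.
#'
#' @param lipid A [parse_lipid_name()] result.
#' @return An object of class `molecular_formula`: named integer vector of
#'   element (or isotope) counts.
#' @examples
#' build_formula(parse_lipid_name("PC(34:1)"))   # C42 H82 N O8 P
#' @export
build_formula <- function(lipid) {
  stopifnot(inherits(lipid, "lipid_species"))
  C <- lipid$total_acyl_carbons
  D <- lipid$total_double_bonds
  counts <- switch(lipid$lipid_class,
    PC = c(C = C + 8L, H = 2L * C - 2L * D + 16L, N = 1L, O = 8L, P = 1L),
    PE = c(C = C + 5L, H = 2L * C - 2L * D + 10L, N = 1L, O = 8L, P = 1L),
    PG = c(C = C + 6L, H = 2L * C - 2L * D + 11L, O = 10L, P = 1L),
    SHexCer = {
      if (!identical(lipid$sphingoid, c(18L, 1L))) {
        stop("only the d18:1 sphingoid base is supported", call. = FALSE)
      }
      n_ac <- lipid$chains[1, 1]
      n_db <- lipid$chains[1, 2]
      c(C = 24L + n_ac, H = 45L + 2L * n_ac - 2L * n_db,
        N = 1L, O = 11L, S = 1L)
    },
    stop("unsupported lipid class '", lipid$lipid_class, "'", call. = FALSE)
  )
  if (counts[["H"]] < 0L) {
    stop("over-unsaturated composition: hydrogen count would be negative for ",
         lipid$name, call. = FALSE)
  }
  k <- lipid$label_extra_neutrons
  if (k > 0L) {
    if (counts[["H"]] < k) stop("label exceeds available hydrogens",
                                call. = FALSE)
    counts[["H"]] <- counts[["H"]] - k
    counts <- c(counts, D = as.integer(k))
  }
  counts <- counts[counts > 0L]
  class(counts) <- "molecular_formula"
  counts
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ",
      paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""),
             collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A [build_formula()] result (or named count vector).
#' @param table A [mass_table()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(build_formula(parse_lipid_name("PC(34:1)")))  # 759.5778
#' @export
monoisotopic_mass <- function(formula, table = mass_table()) {
  counts <- unclass(formula)
  if (length(counts) == 0L) return(0)
  syms <- names(counts)
  unknown <- setdiff(syms, names(table$element_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(counts * table$element_masses[syms])
}

#' Theoretical m/z of a lipid adduct ion
#'
#' Singly charged throughout; the adduct mass delta includes the electron
#' mass, so `[M+H]+` adds 1.007276 Da and `[M-H]-` subtracts it.
#'
#' @param lipid A [parse_lipid_name()] result (or a name to parse).
#' @param adduct Adduct name, e.g. `"[M+H]+"` (see [adduct_table()]).
#' @param table A [mass_table()].
#' @return An object of class `ion_species`: list with `lipid`, `adduct`,
#'   `polarity` and `theoretical_mz`.
#' @examples
#' adduct_mz("PE(40:6)", "[M+H]+")$theoretical_mz   # 792.5538
#' @export
adduct_mz <- function(lipid, adduct, table = mass_table()) {
  if (is.character(lipid)) lipid <- parse_lipid_name(lipid)
  add <- adduct_by_name(adduct, table)
  m <- monoisotopic_mass(build_formula(lipid), table)
  out <- list(
    lipid = lipid,
    adduct = add$name,
    polarity = add$polarity,
    theoretical_mz = m + add$mass_delta
  )
  class(out) <- "ion_species"
  out
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s %s  m/z %.4f\n",
              x$lipid$name, x$adduct, x$theoretical_mz))
  invisible(x)
}

#' Symmetric ppm tolerance window
#'
#' @param mz Center m/z (Da), positive.
#' @param ppm_halfwidth Half-width in parts per million, non-negative.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' ppm_window(800, 5)
#' @export
ppm_window <- function(mz, ppm_halfwidth) {
  stopifnot(all(mz > 0), all(ppm_halfwidth >= 0))
  c(lo = mz * (1 - ppm_halfwidth * 1e-6),
    hi = mz * (1 + ppm_halfwidth * 1e-6))
}

#' Enumerate near-isobaric adduct ion pairs
#'
#' Scans every combination of lipid class, total composition and adduct in
#' the given ranges and reports all unordered pairs of distinct ion species
#' whose m/z differ by at most `tol_mda` millidalton, sorted by increasing
#' gap. The classic family in this panel is the sodiated PC versus the
#' protonated PC with two more acyl carbons and three more double bonds,
#' which differ by only ~2.4 mDa.
#'
#' @param classes Character vector of lipid classes (`"PC"`, `"PE"`, `"PG"`).
#' @param adducts Character vector of adduct names.
#' @param carbon_range Integer range `c(min, max)` of total acyl carbons.
#' @param db_range Integer range `c(min, max)` of total double bonds.
#' @param tol_mda Gap tolerance in mDa (> 0 returns pairs; 0 returns none).
#' @param table A [mass_table()].
#' @return Data frame with one row per pair: names, adducts, m/z values and
#'   `delta_mda` (absolute gap in mDa), sorted ascending by `delta_mda`.
#' @examples
#' hits <- find_near_isobars("PC", c("[M+H]+", "[M+Na]+"),
#'                           c(36, 40), c(0, 4), tol_mda = 5)
#' head(hits)
#' @export
find_near_isobars <- function(classes, adducts, carbon_range, db_range,
                              tol_mda, table = mass_table()) {
  stopifnot(length(carbon_range) == 2L, length(db_range) == 2L, tol_mda >= 0)
  grid <- expand.grid(
    class = classes, carbons = seq(carbon_range[1], carbon_range[2]),
    db = seq(db_range[1], db_range[2]), adduct = adducts,
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$db <= grid$carbons, , drop = FALSE]
  ions <- mapply(function(cl, cc, dd, ad) {
    lip <- structure(list(
      lipid_class = cl, total_acyl_carbons = cc, total_double_bonds = dd,
      chains = NULL, sphingoid = NULL, label_extra_neutrons = 0L,
      name = sprintf("%s(%d:%d)", cl, cc, dd)
    ), class = "lipid_species")
    adduct_mz(lip, ad, table)$theoretical_mz
  }, grid$class, grid$carbons, grid$db, grid$adduct)
  grid$mz <- as.numeric(ions)
  grid$name <- sprintf("%s(%d:%d)", grid$class, grid$carbons, grid$db)

  # windowed scan over the sorted m/z list
  o <- order(grid$mz)
  g <- grid[o, , drop = FALSE]
  n <- nrow(g)
  tol <- tol_mda * 1e-3
  ii <- integer(0); jj <- integer(0)
  if (n >= 2L && tol > 0) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && g$mz[j] - g$mz[i] <= tol) {
        ii <- c(ii, i); jj <- c(jj, j)
        j <- j + 1L
      }
    }
  }
  # drop duplicated grid entries (same ion listed twice cannot occur; a
  # zero-gap pair of identical class+composition+adduct is excluded anyway)
  same <- g$name[ii] == g$name[jj] & g$adduct[ii] == g$adduct[jj]
  ii <- ii[!same]; jj <- jj[!same]
  out <- data.frame(
    name_a = g$name[ii], adduct_a = g$adduct[ii], mz_a = g$mz[ii],
    name_b = g$name[jj], adduct_b = g$adduct[jj], mz_b = g$mz[jj],
    delta_mda = abs(g$mz[jj] - g$mz[ii]) * 1e3,
    stringsAsFactors = FALSE
  )
  out[order(out$delta_mda), , drop = FALSE]
}

#' Can two m/z values be resolved at a given Orbitrap resolution?
#'
#' Uses FT-type resolution scaling R(m) = R200 * sqrt(200 / m): two peaks
#' count as resolved when their separation is at least one FWHM at the mean
#' m/z, FWHM = m / R(m).
#'
#' @param mz_a,mz_b Positive m/z values.
#' @param resolution_at_200 Resolving power specified at m/z 200
#'   (e.g. 280000 or 70000).
#' @return `TRUE` if the pair is resolvable.
#' @examples
#' resolvable(866.660, 866.6624, 280000)   # 2.4 mDa apart: FALSE
#' @export
resolvable <- function(mz_a, mz_b, resolution_at_200) {
  stopifnot(mz_a > 0, mz_b > 0, resolution_at_200 > 0)
  m <- (mz_a + mz_b) / 2
  fwhm <- m / (resolution_at_200 * sqrt(200 / m))
  abs(mz_a - mz_b) >= fwhm
}
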