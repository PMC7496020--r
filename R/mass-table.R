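#' Monoisotopic atomic mass table
#'
#' Returns the fixed table of monoisotopic atomic masses used for every m/z
#' computed by this package, together with the electron and proton masses.
#' The table is embedded as constants rather than read from a configurable
#' source so that all reported masses are reproducible.
#'
#' @return An object of class `mass_table`: a list with `element_masses`
#'   (named numeric vector, Da), `electron_mass` (Da) and `proton_mass` (Da).
#' @examples
#' mt <- mass_table()
#' mt$element_masses[["C"]]
#' @export
mass_table <- function() {
  elements <- c(
    H  = 1.0078250319,
    D  = 2.0141018,
    C  = 12,
    N  = 14.0030740,
    O  = 15.9949146,
    Na = 22.9897693,
    P  = 30.9737615,
    S  = 31.9720707,
    K  = 38.9637065
  )
  electron <- 0.0005486
  out <- list(
    element_masses = elements,
    electron_mass = electron,
    proton_mass = elements[["H"]] - electron
  )
  class(out) <- "mass_table"
  out
}

#' Supported adduct ion types
#'
#' The five singly charged adducts used throughout: protonated, sodiated and
#' potassiated species in positive mode, and the deprotonated species and the
#' acetate adduct (used for PC quantification by LC-MS) in negative mode.
#' All mass deltas include the electron-mass correction for the charged
#' species, so they differ by ~0.55 mDa from neutral-fragment arithmetic.
#'
#' @param table A [mass_table()].
#' @return A data frame with columns `name`, `polarity` (`"+"` or `"-"`),
#'   `mass_delta` (Da) and `charge` (always 1).
#' @examples
#' adduct_table()
#' @export
adduct_table <- function(table = mass_table()) {
  em <- table$element_masses
  e <- table$electron_mass
  acetate <- 2 * em[["C"]] + 3 * em[["H"]] + 2 * em[["O"]]
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-", "[M+OAc]-"),
    polarity = c("+", "+", "+", "-", "-"),
    mass_delta = c(
      em[["H"]] - e,
      em[["Na"]] - e,
      em[["K"]] - e,
      -(em[["H"]] - e),
      acetate + e
    ),
    charge = 1L,
    stringsAsFactors = FALSE
  )
}

# Resolve one adduct row by name; accepts the unicode minus variant too.
adduct_by_name <- function(name, table = mass_table()) {
  tab <- adduct_table(table)
  name <- gsub("−", "-", name)
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown adduct '", name, "'; supported: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  tab[i, , drop = FALSE]
}
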