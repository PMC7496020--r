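#' Extract a ppm-tolerant ion image
#'
#' Builds the per-pixel intensity map of one ion: within each pixel, all
#' centroids whose m/z falls inside the symmetric ppm window around the
#' ion's theoretical m/z are aggregated (summed by default); pixels with no
#' matching centroid get 0.
#'
#' @param ds An [msi_dataset()].
#' @param ion An `ion_species` from [adduct_mz()], or a bare m/z value.
#' @param ppm_halfwidth Window half-width, ppm (default 5).
#' @param aggregation `"sum"` or `"max"` over in-window centroids.
#' @return Object of class `ion_image`: list with `grid` (matrix, rows x
#'   cols of the dataset bounding box), `mz`, `ppm_halfwidth`,
#'   `aggregation`, `pixel_size`.
#' @export
extract_ion_image <- function(ds, ion, ppm_halfwidth = 5,
                              aggregation = c("sum", "max")) {
  stopifnot(inherits(ds, "msi_dataset"))
  aggregation <- match.arg(aggregation)
  if (inherits(ion, "ion_species")) {
    if (ion$polarity != ds$polarity) {
      stop("ion polarity (", ion$polarity,
           ") does not match dataset polarity (", ds$polarity, ")",
           call. = FALSE)
    }
    mz <- ion$theoretical_mz
  } else {
    mz <- as.numeric(ion)
  }
  w <- ppm_window(mz, ppm_halfwidth)
  p <- ds$peaks
  sel <- p$mz >= w[1] & p$mz <= w[2]
  vals <- numeric(nrow(ds$coords))
  if (any(sel)) {
    px <- p$pixel[sel]
    it <- p$intensity[sel]
    if (aggregation == "sum") {
      s <- rowsum(it, group = px)
      vals[as.integer(rownames(s))] <- s[, 1]
    } else {
      o <- order(px, -it)
      keep <- !duplicated(px[o])
      vals[px[o][keep]] <- it[o][keep]
    }
  }
  sh <- grid_shape(ds)
  grid <- matrix(NA_real_, sh[1], sh[2])
  grid[cbind(ds$coords$y + 1L, ds$coords$x + 1L)] <- vals
  grid[is.na(grid)] <- 0
  out <- list(grid = grid, mz = mz, ppm_halfwidth = ppm_halfwidth,
              aggregation = aggregation, pixel_size = ds$pixel_size)
  class(out) <- "ion_image"
  out
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf(
    "<ion_image> m/z %.4f +/- %g ppm (%s), %dx%d grid, max %.3g\n",
    x$mz, x$ppm_halfwidth, x$aggregation, nrow(x$grid), ncol(x$grid),
    max(x$grid)))
  invisible(x)
}

#' Display an ion image
#'
#' @param x An [extract_ion_image()] result.
#' @param main Title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.ion_image <- function(x, main = sprintf("m/z %.4f", x$mz), ...) {
  z <- t(x$grid[nrow(x$grid):1, , drop = FALSE])
  graphics::image(z, main = main, axes = FALSE, useRaster = TRUE, ...)
  invisible(x)
}

#' Clip intensity hotspots by quantile
#'
#' Intensities above the image's `quantile` value (sorted-order linear
#' interpolation, i.e. the default quantile definition) are clipped to that
#' value; everything else is unchanged. The accepted stand-in for the
#' hotspot-removal feature of commercial MSI software, whose exact rule is
#' undocumented. Idempotent.
#'
#' @param img An [extract_ion_image()] result.
#' @param quantile Clipping quantile in (0, 1]; 1 is the identity.
#' @return A clipped `ion_image`.
#' @export
remove_hotspots <- function(img, quantile = 0.99) {
  stopifnot(inherits(img, "ion_image"), quantile > 0, quantile <= 1)
  q <- stats::quantile(img$grid, probs = quantile, names = FALSE, type = 7)
  img$grid <- pmin(img$grid, q)
  img
}

#' Mean intensity of an ion image over an ROI
#'
#' Arithmetic mean over the ROI's pixels, zero-intensity pixels included —
#' mirroring ROI mean statistics of MSI software.
#'
#' @param img An [extract_ion_image()] result.
#' @param roi An [roi()] object.
#' @return Mean intensity.
#' @export
roi_mean_intensity <- function(img, roi) {
  stopifnot(inherits(img, "ion_image"), inherits(roi, "roi"))
  if (nrow(roi$pixels) == 0L) stop("empty ROI", call. = FALSE)
  idx <- cbind(roi$pixels$y + 1L, roi$pixels$x + 1L)
  if (any(idx[, 1] > nrow(img$grid)) || any(idx[, 2] > ncol(img$grid))) {
    stop("ROI extends beyond image grid", call. = FALSE)
  }
  mean(img$grid[idx])
}

#' Summed ROI intensity across a lipid's adduct species
#'
#' The MSI-side quantity behind a response factor: the sum over the lipid's
#' accessible adduct species of the ROI mean intensity of each species'
#' ion image (optionally hotspot-clipped first). In negative mode the
#' deprotonated species alone is conventionally used.
#'
#' @param ds An [msi_dataset()].
#' @param lipid Lipid name or [parse_lipid_name()] result.
#' @param adducts Character vector of adduct names; polarity must match the
#'   dataset.
#' @param roi An [roi()] object.
#' @param ppm_halfwidth Window half-width, ppm.
#' @param hotspot_quantile `NULL` for raw intensities (the default used for
#'   response factors), or a quantile passed to [remove_hotspots()].
#' @return Summed mean intensity.
#' @export
summed_adduct_intensity <- function(ds, lipid, adducts, roi,
                                    ppm_halfwidth = 5,
                                    hotspot_quantile = NULL) {
  stopifnot(length(adducts) >= 1L)
  if (is.character(lipid)) lipid <- parse_lipid_name(lipid)
  total <- 0
  for (a in adducts) {
    ion <- adduct_mz(lipid, a)
    img <- extract_ion_image(ds, ion, ppm_halfwidth)
    if (!is.null(hotspot_quantile)) {
      img <- remove_hotspots(img, hotspot_quantile)
    }
    total <- total + roi_mean_intensity(img, roi)
  }
  total
}
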