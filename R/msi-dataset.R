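#' Construct an MSI dataset of pixel-indexed centroid spectra
#'
#' The in-memory container for mass spectrometry imaging data: a table of
#' unique pixel coordinates and one long table of centroid peaks, each
#' assigned to a pixel. Coordinates are 0-based, `x` = column increasing
#' right, `y` = row increasing down (imzML 1-based indices are converted on
#' read/write). Within each pixel the m/z values are kept strictly
#' ascending.
#'
#' @param coords Data frame with integer columns `x`, `y`; rows unique.
#' @param peaks Data frame with columns `pixel` (row index into `coords`),
#'   `mz` and `intensity` (non-negative).
#' @param pixel_size Pixel edge length in micrometers.
#' @param polarity `"+"` or `"-"`.
#' @param modality `"MALDI"` or `"MALDI2"`.
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, peaks, pixel_size, polarity = "+",
                        modality = "MALDI") {
  stopifnot(all(c("x", "y") %in% names(coords)),
            all(c("pixel", "mz", "intensity") %in% names(peaks)),
            pixel_size > 0)
  if (anyDuplicated(coords[c("x", "y")])) {
    stop("pixel coordinates must be unique", call. = FALSE)
  }
  if (any(peaks$intensity < 0)) stop("negative intensities", call. = FALSE)
  o <- order(peaks$pixel, peaks$mz)
  peaks <- peaks[o, c("pixel", "mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  dup <- duplicated(peaks[c("pixel", "mz")])
  if (any(dup)) {
    stop("m/z values must be strictly ascending within a pixel",
         call. = FALSE)
  }
  out <- list(coords = coords[c("x", "y")], peaks = peaks,
              pixel_size = pixel_size, polarity = polarity,
              modality = modality)
  class(out) <- "msi_dataset"
  out
}

#' @export
print.msi_dataset <- function(x, ...) {
  sh <- grid_shape(x)
  cat(sprintf(
    "<msi_dataset> %d pixels on a %dx%d grid, %d centroids\n  %s, %s mode, %g um pixels\n",
    nrow(x$coords), sh[1], sh[2], nrow(x$peaks), x$modality,
    if (x$polarity == "+") "positive" else "negative", x$pixel_size))
  invisible(x)
}

# Grid bounding box as c(rows, cols); coords are 0-based.
grid_shape <- function(ds) {
  c(max(ds$coords$y) + 1L, max(ds$coords$x) + 1L)
}

# Per-pixel total ion count, aligned with rows of ds$coords.
pixel_tic <- function(ds) {
  tic <- numeric(nrow(ds$coords))
  s <- rowsum(ds$peaks$intensity, group = ds$peaks$pixel)
  tic[as.integer(rownames(s))] <- s[, 1]
  tic
}

#' Normalize each pixel spectrum to its total ion count
#'
#' Divides every centroid intensity by the pixel's summed intensity, so each
#' nonzero pixel's TIC becomes exactly 1. Pixels with zero TIC are left as
#' zeros. TIC normalization is provided for inspection; response factors are
#' computed from raw intensities by default, because in tissue with very
#' unevenly distributed dominant species TIC scaling introduces bias of its
#' own rather than removing it.
#'
#' @param ds An [msi_dataset()].
#' @return A new `msi_dataset` with normalized intensities.
#' @export
tic_normalize <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  tic <- pixel_tic(ds)
  denom <- tic[ds$peaks$pixel]
  ok <- denom > 0
  ds$peaks$intensity[ok] <- ds$peaks$intensity[ok] / denom[ok]
  ds
}
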