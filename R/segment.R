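#' Segment an MSI dataset by spectral k-means
#'
#' Mirrors the segmentation practice of MSI software: feature vectors are
#' the per-pixel intensities of the `n_features` most abundant dataset-wide
#' peaks (m/z values binned at the given ppm tolerance), TIC-normalized per
#' pixel; denoising applies a median filter to each feature channel on the
#' pixel grid (weak = 3x3, strong = 5x5); pixels are then clustered with
#' k-means under a fixed seed (multiple k-means++-style restarts via
#' `nstart`).
#'
#' @param ds An [msi_dataset()].
#' @param k Number of clusters (>= 2); remember one cluster is usually the
#'   off-tissue background.
#' @param denoise `"none"`, `"weak"` or `"strong"`.
#' @param seed RNG seed for the clustering.
#' @param n_features Number of peak features (default 50).
#' @param ppm_halfwidth Binning tolerance for collapsing jittered centroid
#'   m/z values into one peak feature (default 5 ppm).
#' @return Object of class `segmentation_map`: list with `labels` (integer
#'   matrix, values 0..k-1, same shape as the dataset grid; grid cells
#'   without a pixel are `NA`), `k`, `seed`, `feature_mz` (the m/z of the
#'   features used).
#' @export
segment_msi <- function(ds, k, denoise = c("weak", "none", "strong"),
                        seed = 1L, n_features = 50L, ppm_halfwidth = 5) {
  stopifnot(inherits(ds, "msi_dataset"), k >= 2L)
  if (k > nrow(ds$coords)) stop("k exceeds pixel count", call. = FALSE)
  denoise <- match.arg(denoise)

  bins <- bin_mz(ds$peaks$mz, ppm_halfwidth)
  totals <- rowsum(ds$peaks$intensity, group = bins$bin)
  top <- order(-totals[, 1])[seq_len(min(n_features, nrow(totals)))]
  top_ids <- as.integer(rownames(totals))[top]

  npix <- nrow(ds$coords)
  feat <- matrix(0, npix, length(top_ids))
  sel <- bins$bin %in% top_ids
  col_of <- match(bins$bin[sel], top_ids)
  feat_idx <- cbind(ds$peaks$pixel[sel], col_of)
  # accumulate (a pixel can hold several centroids in one bin)
  acc <- rowsum(ds$peaks$intensity[sel],
                group = (feat_idx[, 2] - 1L) * npix + feat_idx[, 1])
  feat[as.integer(rownames(acc))] <- acc[, 1]

  tic <- pixel_tic(ds)
  nz <- tic > 0
  feat[nz, ] <- feat[nz, , drop = FALSE] / tic[nz]

  radius <- c(none = 0L, weak = 1L, strong = 2L)[[denoise]]
  if (radius > 0L) {
    sh <- grid_shape(ds)
    idx <- cbind(ds$coords$y + 1L, ds$coords$x + 1L)
    for (j in seq_len(ncol(feat))) {
      g <- matrix(0, sh[1], sh[2])   # grid cells without a pixel count as 0
      g[idx] <- feat[, j]
      g <- median_filter(g, radius)
      feat[, j] <- g[idx]
    }
  }

  set.seed(seed)
  km <- stats::kmeans(feat, centers = k, nstart = 10L, iter.max = 100L)
  sh <- grid_shape(ds)
  labels <- matrix(NA_integer_, sh[1], sh[2])
  labels[cbind(ds$coords$y + 1L, ds$coords$x + 1L)] <- km$cluster - 1L
  out <- list(labels = labels, k = as.integer(k), seed = as.integer(seed),
              feature_mz = bins$center[match(top_ids, bins$bin)])
  class(out) <- "segmentation_map"
  out
}

#' @export
print.segmentation_map <- function(x, ...) {
  tab <- table(x$labels)
  cat("<segmentation_map> k = ", x$k, "; pixels per label: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Collapse sorted m/z values into bins: a new bin starts wherever the gap to
# the previous value exceeds the (2 x ppm) tolerance at that mass.
bin_mz <- function(mz, ppm_halfwidth) {
  o <- order(mz)
  s <- mz[o]
  gap <- c(Inf, diff(s))
  new_bin <- gap > s * 2 * ppm_halfwidth * 1e-6
  bin_sorted <- cumsum(new_bin)
  bin <- integer(length(mz))
  bin[o] <- bin_sorted
  centers <- tapply(s, bin_sorted, stats::median)
  list(bin = bin, center = as.numeric(centers))
}

# Median filter with edge replication, fully vectorized: the window values
# are collected as shifted copies and the per-cell median is computed with a
# compare-exchange sorting network (no per-pixel loop).
median_filter <- function(g, radius = 1L) {
  if (radius == 0L) return(g)
  shifts <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  nr <- nrow(g); nc <- ncol(g)
  cols <- lapply(seq_len(nrow(shifts)), function(i) {
    ri <- pmin(pmax(seq_len(nr) + shifts$dy[i], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + shifts$dx[i], 1L), nc)
    as.vector(g[ri, ci, drop = FALSE])
  })
  m <- do.call(cbind, cols)
  matrix(row_median_small(m), nr, nc)
}

# Row-wise median of a matrix with few columns via partial sorting on
# columns (vectorized compare-exchange).
row_median_small <- function(m) {
  k <- ncol(m)
  # selection of the middle order statistic(s) by repeated column-wise
  # min-extraction: k is at most 25 (5x5 window), so this stays cheap
  half <- (k + 1L) %/% 2L
  res_lo <- NULL
  for (step in seq_len(half)) {
    mins <- m[, 1]
    arg <- rep(1L, nrow(m))
    for (j in 2:k) {
      smaller <- m[, j] < mins
      mins[smaller] <- m[smaller, j]
      arg[smaller] <- j
    }
    res_lo <- mins
    m[cbind(seq_len(nrow(m)), arg)] <- Inf
  }
  if (k %% 2L == 1L) return(res_lo)
  # even window: average the two central order statistics
  mins <- m[, 1]
  for (j in 2:k) mins <- pmin(mins, m[, j])
  (res_lo + mins) / 2
}

#' Build an ROI from segmentation labels
#'
#' @param map A [segment_msi()] result.
#' @param labels Integer label(s) to collect.
#' @param name ROI name (e.g. `"WM"`, `"ML"`).
#' @param pixel_size Pixel edge length, micrometers.
#' @return An [roi()] with physical area `pixel count x (pixel_size/1000)^2`
#'   mm^2.
#' @export
roi_from_segments <- function(map, labels, name, pixel_size) {
  stopifnot(inherits(map, "segmentation_map"))
  present <- unique(as.vector(map$labels))
  missing <- setdiff(labels, present)
  if (length(missing)) {
    stop("label(s) not in segmentation: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sel <- which(array(map$labels %in% labels, dim = dim(map$labels)),
               arr.ind = TRUE)
  if (nrow(sel) == 0L) stop("empty ROI selection", call. = FALSE)
  roi(data.frame(x = sel[, 2] - 1L, y = sel[, 1] - 1L), name = name,
      pixel_size = pixel_size)
}

#' A labeled region of interest
#'
#' @param pixels Data frame of 0-based `x`, `y` pixel coordinates.
#' @param name Label.
#' @param pixel_size Pixel edge length, micrometers.
#' @return Object of class `roi` with `pixels`, `name`, `area` (mm^2).
#' @export
roi <- function(pixels, name, pixel_size) {
  stopifnot(all(c("x", "y") %in% names(pixels)), nrow(pixels) > 0L,
            pixel_size > 0)
  out <- list(pixels = pixels[c("x", "y")], name = name,
              area = nrow(pixels) * (pixel_size / 1000)^2)
  class(out) <- "roi"
  out
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> '%s': %d pixels, %.4f mm^2\n", x$name,
              nrow(x$pixels), x$area))
  invisible(x)
}
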