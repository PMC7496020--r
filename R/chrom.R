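#' Construct an LC-MS chromatogram run
#'
#' Time-resolved centroid data stored in long (columnar) form: one row per
#' (retention time, m/z, intensity) triple, plus the full scan-time grid so
#' that scans without matching centroids still contribute zero points to
#' extracted ion chromatograms.
#'
#' @param points Data frame `rt` (min), `mz`, `intensity`.
#' @param rt_grid Strictly increasing vector of scan times (min); defaults
#'   to the sorted unique `rt` values of `points`.
#' @param polarity `"+"` or `"-"`.
#' @param sample_id Identifier.
#' @return Object of class `chrom_run`.
#' @export
chrom_run <- function(points, rt_grid = NULL, polarity = "-",
                      sample_id = "run") {
  stopifnot(all(c("rt", "mz", "intensity") %in% names(points)))
  if (is.null(rt_grid)) rt_grid <- sort(unique(points$rt))
  if (is.unsorted(rt_grid, strictly = TRUE)) {
    stop("rt_grid must be strictly increasing", call. = FALSE)
  }
  o <- order(points$rt, points$mz)
  points <- points[o, c("rt", "mz", "intensity"), drop = FALSE]
  rownames(points) <- NULL
  out <- list(points = points, rt_grid = rt_grid, polarity = polarity,
              sample_id = sample_id)
  class(out) <- "chrom_run"
  out
}

#' @export
print.chrom_run <- function(x, ...) {
  cat(sprintf(
    "<chrom_run> '%s': %d scans over %.2f-%.2f min, %d centroids (%s mode)\n",
    x$sample_id, length(x$rt_grid), min(x$rt_grid), max(x$rt_grid),
    nrow(x$points), if (x$polarity == "+") "positive" else "negative"))
  invisible(x)
}

#' Read and write chromatogram runs as columnar CSV
#'
#' The on-disk format is a plain CSV of `rt`, `mz`, `intensity` triples with
#' the scan grid and metadata in `#`-prefixed header lines, readable by any
#' table tool and round-tripping exactly.
#'
#' @param run A [chrom_run()].
#' @param path CSV file path.
#' @return `write_chrom_csv()`: `path` invisibly; `read_chrom_csv()`: a
#'   [chrom_run()].
#' @export
write_chrom_csv <- function(run, path) {
  stopifnot(inherits(run, "chrom_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id: %s", run$sample_id),
    sprintf("# polarity: %s", run$polarity),
    sprintf("# rt_grid: %s",
            paste(format(run$rt_grid, digits = 15, trim = TRUE),
                  collapse = " "))
  ), con)
  utils::write.table(
    data.frame(rt = format(run$points$rt, digits = 15, trim = TRUE),
               mz = format(run$points$mz, digits = 15, trim = TRUE),
               intensity = format(run$points$intensity, digits = 15,
                                  trim = TRUE)),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chrom_csv
#' @export
read_chrom_csv <- function(path) {
  lines <- readLines(path, n = 3L)
  meta <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), lines,
                                 value = TRUE)[1])
  points <- utils::read.csv(path, comment.char = "#")
  chrom_run(points,
            rt_grid = as.numeric(strsplit(meta("rt_grid"), " ")[[1]]),
            polarity = meta("polarity"), sample_id = meta("sample_id"))
}

#' Extract an ion chromatogram
#'
#' Sums, per scan, all centroid intensities within the symmetric ppm window
#' around the ion's theoretical m/z. Scans with no matching centroid yield
#' zero, so the XIC always spans the full scan grid.
#'
#' @param run A [chrom_run()].
#' @param ion An `ion_species` from [adduct_mz()], or a bare m/z value.
#' @param ppm_halfwidth Window half-width, ppm (default 5).
#' @return Object of class `xic`: list with `rt`, `intensity`, `mz`
#'   (window center) and `ppm_halfwidth`.
#' @export
extract_xic <- function(run, ion, ppm_halfwidth = 5) {
  stopifnot(inherits(run, "chrom_run"))
  if (inherits(ion, "ion_species")) {
    if (ion$polarity != run$polarity) {
      stop("ion polarity (", ion$polarity, ") does not match run polarity (",
           run$polarity, ")", call. = FALSE)
    }
    mz <- ion$theoretical_mz
  } else {
    mz <- as.numeric(ion)
  }
  w <- ppm_window(mz, ppm_halfwidth)
  p <- run$points
  sel <- p$mz >= w[1] & p$mz <= w[2]
  intensity <- numeric(length(run$rt_grid))
  if (any(sel)) {
    idx <- findInterval(p$rt[sel], run$rt_grid)
    # scans are on the grid; guard against floating drift
    idx[idx < 1L] <- 1L
    s <- rowsum(p$intensity[sel], group = idx)
    intensity[as.integer(rownames(s))] <- s[, 1]
  }
  out <- list(rt = run$rt_grid, intensity = intensity, mz = mz,
              ppm_halfwidth = ppm_halfwidth)
  class(out) <- "xic"
  out
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> m/z %.4f +/- %g ppm, %d scans, max intensity %.3g\n",
              x$mz, x$ppm_halfwidth, length(x$rt), max(x$intensity)))
  invisible(x)
}

#' Detect chromatographic peaks in an XIC
#'
#' Local maxima exceeding `baseline + min_snr * noise`, where the baseline
#' is the XIC median and the noise scale is the median absolute deviation
#' (with a small floor so flat-zero baselines do not admit everything).
#' Each peak's bounds are placed at the nearest valley on each side or at
#' the first point below 1% of apex height, whichever is closer to the
#' apex. Peaks narrower than `min_width_scans` are dropped; results are
#' sorted by area, largest first.
#'
#' @param xic An [extract_xic()] result.
#' @param min_snr Signal-to-noise threshold above baseline (default 3).
#' @param min_width_scans Minimal peak width in scans (default 3).
#' @return Data frame of class `chrom_peaks`: `apex_rt`, `left_rt`,
#'   `right_rt`, `height`, `area` (trapezoidal, intensity x min).
#' @export
detect_peaks <- function(xic, min_snr = 3, min_width_scans = 3L) {
  y <- xic$intensity
  n <- length(y)
  if (n == 0L || all(y == 0)) {
    return(empty_peaks())
  }
  baseline <- stats::median(y)
  noise <- stats::mad(y)
  floor_ <- 1e-9 * max(y)
  thr <- baseline + min_snr * max(noise, floor_)

  apex <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- apex[y[apex] > thr & y[apex] > 0]
  if (!length(apex)) return(empty_peaks())

  # walk outward while descending; stop at a valley or below 1% of apex
  bounds <- function(a) {
    cut <- 0.01 * y[a]
    l <- a
    while (l > 1L && y[l - 1L] <= y[l] && y[l] > cut) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] <= y[r] && y[r] > cut) r <- r + 1L
    c(l, r)
  }
  rows <- lapply(apex, function(a) {
    b <- bounds(a)
    if (b[2] - b[1] + 1L < min_width_scans) return(NULL)
    area <- pracma::trapz(xic$rt[b[1]:b[2]], y[b[1]:b[2]])
    data.frame(apex_rt = xic$rt[a], left_rt = xic$rt[b[1]],
               right_rt = xic$rt[b[2]], height = y[a], area = area)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_peaks())
  out <- do.call(rbind, rows)
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chrom_peaks", "data.frame")
  out
}

empty_peaks <- function() {
  out <- data.frame(apex_rt = numeric(0), left_rt = numeric(0),
                    right_rt = numeric(0), height = numeric(0),
                    area = numeric(0))
  class(out) <- c("chrom_peaks", "data.frame")
  out
}

#' Trapezoidal area of a peak
#'
#' @param xic An [extract_xic()] result.
#' @param peak One-row slice of a [detect_peaks()] table, or any list with
#'   `left_rt` and `right_rt`.
#' @return Area in intensity x min.
#' @export
integrate_peak <- function(xic, peak) {
  l <- peak$left_rt
  r <- peak$right_rt
  if (l > r) stop("inverted peak bounds", call. = FALSE)
  sel <- xic$rt >= l & xic$rt <= r
  if (sum(sel) < 2L) return(0)
  pracma::trapz(xic$rt[sel], xic$intensity[sel])
}
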