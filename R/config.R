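#' Pipeline configuration
#'
#' Collects every fixed constant of the workflow in one validated object:
#' the 5 ppm assignment tolerance, the 0.99 hotspot-clipping quantile, the
#' segmentation settings, the 20 um section thickness and 20 uL extract
#' volume used for volume normalization, the 20% replicate-CV exclusion
#' threshold for calibration levels, the 5% isobaric-interference
#' threshold, the adduct sets evaluated per polarity, and the simulation
#' settings for the synthetic demo.
#'
#' @param ppm_halfwidth Ion-assignment window half-width, ppm.
#' @param hotspot_quantile Clipping quantile for [remove_hotspots()].
#' @param segmentation List: `k`, `seed`, `denoise`, `n_features`.
#' @param thickness_mm Section thickness, mm.
#' @param extract_volume_L Extract volume, L.
#' @param cv_threshold Calibration replicate-CV exclusion threshold.
#' @param interference_threshold Maximal tolerated interferent area
#'   fraction.
#' @param adducts List with `positive` and `negative` character vectors.
#' @param msi List of [msi_sim_config()] arguments for the synthetic demo
#'   (`grid_shape`, `pixel_size`, `ppm_jitter_sd`, `noise_cv`,
#'   `hotspot_fraction`, `hotspot_multiplier`).
#' @param lcms List of synthetic LC-MS settings (`noise_cv`).
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ppm_halfwidth = 5, hotspot_quantile = 0.99,
                            segmentation = list(), thickness_mm = 0.020,
                            extract_volume_L = 20e-6, cv_threshold = 0.2,
                            interference_threshold = 0.05,
                            adducts = list(), msi = list(), lcms = list(),
                            seed = 1L) {
  seg_def <- list(k = 3L, seed = 1L, denoise = "weak", n_features = 50L)
  add_def <- list(positive = c("[M+H]+", "[M+Na]+", "[M+K]+"),
                  negative = "[M-H]-")
  msi_def <- list(grid_shape = c(60L, 60L), pixel_size = 30,
                  ppm_jitter_sd = 1, noise_cv = 0.1,
                  hotspot_fraction = 0, hotspot_multiplier = 1)
  lcms_def <- list(noise_cv = 0.05)
  segmentation <- merge_defaults(segmentation, seg_def, "segmentation")
  adducts <- merge_defaults(adducts, add_def, "adducts")
  msi <- merge_defaults(msi, msi_def, "msi")
  lcms <- merge_defaults(lcms, lcms_def, "lcms")
  stopifnot(ppm_halfwidth >= 0, hotspot_quantile > 0, hotspot_quantile <= 1,
            thickness_mm > 0, extract_volume_L > 0,
            cv_threshold >= 0, interference_threshold >= 0,
            interference_threshold <= 1, segmentation$k >= 2)
  out <- list(ppm_halfwidth = ppm_halfwidth,
              hotspot_quantile = hotspot_quantile,
              segmentation = segmentation, thickness_mm = thickness_mm,
              extract_volume_L = extract_volume_L,
              cv_threshold = cv_threshold,
              interference_threshold = interference_threshold,
              adducts = adducts, msi = msi, lcms = lcms,
              seed = as.integer(seed))
  class(out) <- "pipeline_config"
  out
}

merge_defaults <- function(given, defaults, what) {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, given)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  ppm +/-%g, hotspot q%.2f, thickness %g mm, extract %g L\n",
              x$ppm_halfwidth, x$hotspot_quantile, x$thickness_mm,
              x$extract_volume_L))
  cat(sprintf("  segmentation k=%d seed=%d denoise=%s; seed %d\n",
              x$segmentation$k, x$segmentation$seed,
              x$segmentation$denoise, x$seed))
  invisible(x)
}

#' Load and save pipeline configuration as YAML
#'
#' An empty or absent-keys file yields all defaults; unknown keys are
#' rejected (fail-fast) and out-of-range values raise the same validation
#' errors as [pipeline_config()]. `save_config()` then `load_config()`
#' round-trips to an identical object.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` (or `path` invisibly for `save_config`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("ppm_halfwidth", "hotspot_quantile", "thickness_mm",
                "extract_volume_L", "cv_threshold",
                "interference_threshold", "seed")) {
    if (!is.null(raw[[key]]) && !is.numeric(raw[[key]])) {
      stop("config key '", key, "' must be numeric, got ",
           class(raw[[key]])[1], call. = FALSE)
    }
  }
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @param config A `pipeline_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Order-insensitive hash of a config: canonicalize by recursively sorting
# names, then checksum the serialized text.
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm)) x <- x[order(nm)]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                          digits = NA)
  v <- utf8ToInt(as.character(txt))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
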