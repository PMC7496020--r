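#' Fit an internal-standard external calibration curve
#'
#' The calibration model is ordinary least squares of the mean
#' analyte/IS peak-area ratio against the known concentration:
#' `ratio = slope * conc + intercept`. Before fitting, any level whose
#' replicate ratios vary with CV above `cv_threshold` is excluded — the
#' automated counterpart of dropping concentrations with high deviations in
#' triple determination.
#'
#' @param ratios List (one element per level) of numeric replicate
#'   area ratios, or a matrix with one row per level.
#' @param concentrations Known concentrations, mol/L, one per level.
#' @param cv_threshold Replicate-CV exclusion threshold (default 0.2).
#' @param weights `"none"` (default, unweighted OLS) or `"1/x"` for
#'   inverse-concentration weighting.
#' @param lipid Optional lipid name carried in the object.
#' @return Object of class `calibration_curve` with the per-level table
#'   (`conc`, `mean_ratio`, `cv`, `n`, `excluded`), the underlying
#'   [stats::lm] fit, `slope`, `intercept` and `r_squared`. Supports
#'   `print()`, `summary()`, `coef()`, `predict()` (inverse prediction:
#'   area ratio to concentration), `residuals()` and `plot()`.
#' @examples
#' conc <- c(1e-6, 1e-5, 1e-4)
#' ratios <- lapply(conc, function(cc) rep(1e4 * cc, 3))
#' fit <- fit_calibration(ratios, conc)
#' coef(fit)
#' predict(fit, area_ratio = 0.05)
#' @export
fit_calibration <- function(ratios, concentrations, cv_threshold = 0.2,
                            weights = c("none", "1/x"), lipid = NULL) {
  weights <- match.arg(weights)
  if (is.matrix(ratios)) ratios <- split(ratios, row(ratios))
  stopifnot(length(ratios) == length(concentrations),
            length(ratios) >= 2L)
  mean_ratio <- vapply(ratios, mean, numeric(1))
  cv <- vapply(ratios, function(r) {
    if (length(r) < 2L || mean(r) == 0) return(0)
    stats::sd(r) / mean(r)
  }, numeric(1))
  n <- lengths(ratios)
  excluded <- cv > cv_threshold
  levels <- data.frame(conc = concentrations, mean_ratio = mean_ratio,
                       cv = cv, n = n, excluded = excluded)
  keep <- levels[!levels$excluded, , drop = FALSE]
  if (nrow(keep) < 2L) {
    stop("fewer than 2 calibration levels survive CV exclusion",
         call. = FALSE)
  }
  w <- if (weights == "1/x") 1 / keep$conc else NULL
  fit <- stats::lm(mean_ratio ~ conc, data = keep, weights = w)
  out <- list(
    lipid = lipid,
    levels = levels,
    fit = fit,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    cv_threshold = cv_threshold,
    weights = weights
  )
  if (!is.finite(out$slope) || out$slope == 0) {
    stop("degenerate calibration: slope is zero or non-finite",
         call. = FALSE)
  }
  class(out) <- "calibration_curve"
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>", if (!is.null(x$lipid)) x$lipid else "", "\n")
  cat(sprintf("  slope %.6g per (mol/L), intercept %.6g, R^2 %.6f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d levels, %d excluded (CV > %g)\n", nrow(x$levels),
              sum(x$levels$excluded), x$cv_threshold))
  invisible(x)
}

#' @export
summary.calibration_curve <- function(object, ...) {
  print(object)
  cat("\nPer-level table:\n")
  print(object$levels, digits = 4)
  cat("\nOLS fit on surviving level means:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.calibration_curve <- function(object, ...) {
  stats::residuals(object$fit)
}

#' Back-calculate concentration from an area ratio
#'
#' @param object A [fit_calibration()] result.
#' @param area_ratio Analyte/IS peak-area ratio(s).
#' @param ... Unused.
#' @return Concentration(s), mol/L; negative back-calculations are clamped
#'   to 0 with a warning.
#' @export
predict.calibration_curve <- function(object, area_ratio, ...) {
  conc <- (area_ratio - object$intercept) / object$slope
  if (any(conc < 0)) {
    warning("negative back-calculated concentration clamped to 0")
    conc[conc < 0] <- 0
  }
  conc
}

#' @export
plot.calibration_curve <- function(x, ...) {
  lv <- x$levels
  graphics::plot(lv$conc, lv$mean_ratio, log = "xy",
                 pch = ifelse(lv$excluded, 4, 19),
                 col = ifelse(lv$excluded, "red", "black"),
                 xlab = "concentration (mol/L)", ylab = "area ratio", ...)
  cc <- range(lv$conc[!lv$excluded])
  xs <- exp(seq(log(cc[1]), log(cc[2]), length.out = 50))
  graphics::lines(xs, x$intercept + x$slope * xs, col = "grey40")
  invisible(x)
}
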