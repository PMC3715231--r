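#' Fit an external calibration curve
#'
#' Fits the detector response (peak area) against the loaded analyte mass for
#' one compound. The response factor (RF) is the zero-intercept least-squares
#' slope, i.e. external calibration through the origin; R^2 is the uncentered
#' coefficient of determination of that zero-intercept fit. A mean-of-ratios
#' estimator is available as an alternative.
#'
#' @param loading_ng Numeric vector of standard loadings in ng (>= 2 distinct
#'   values).
#' @param area Peak areas, same length, all >= 0.
#' @param method `"zero_intercept"` (default) or `"mean_ratio"`.
#' @param compound Optional compound label carried into the result.
#' @return An object of class `"calibration_fit"`: list with `compound`,
#'   `rf` (area per ng), `r2`, `n`, `method` and `points`.
#' @examples
#' fit_calibration_curve(c(1.3, 6.52, 13, 26.1, 65.2),
#'                       100 * c(1.3, 6.52, 13, 26.1, 65.2))
#' @export
fit_calibration_curve <- function(loading_ng, area,
                                  method = c("zero_intercept", "mean_ratio"),
                                  compound = NA_character_) {
  method <- match.arg(method)
  if (length(loading_ng) != length(area))
    stop("loading_ng and area must have the same length")
  if (length(loading_ng) < 2L)
    stop("need at least 2 calibration points")
  if (any(!is.finite(loading_ng)) || any(!is.finite(area)))
    stop("calibration points must be finite")
  if (any(area < 0)) stop("areas must be >= 0")
  if (length(unique(loading_ng)) < 2L)
    stop("degenerate calibration design: all loadings identical")
  if (any(loading_ng <= 0)) stop("loadings must be > 0")

  fit <- stats::lm(area ~ 0 + loading_ng)
  rf <- if (method == "zero_intercept") unname(stats::coef(fit)[1])
        else mean(area / loading_ng)
  # uncentered R^2 of the through-origin fit (guaranteed in [0, 1])
  resid <- area - rf * loading_ng
  r2 <- 1 - sum(resid^2) / sum(area^2)
  if (rf <= 0) stop("fitted response factor is not positive")
  structure(list(compound = compound, rf = rf, r2 = r2,
                 n = length(area), method = method,
                 points = data.frame(loading_ng = loading_ng, area = area)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  lbl <- if (is.na(x$compound)) "" else paste0(" [", x$compound, "]")
  cat(sprintf("Calibration fit%s: RF = %.4g area/ng (%s, n = %d, R^2 = %.4f)\n",
              lbl, x$rf, x$method, x$n, x$r2))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) c(rf = object$rf)

#' Coefficient of variation of response factors
#'
#' `CV% = 100 * SD / mean` across batch/day response factors, with the
#' sample (n - 1) standard deviation.
#'
#' @param rf_values Numeric vector of response factors (>= 2 values,
#'   positive mean).
#' @return CV in percent.
#' @examples
#' rf_cv(c(9, 11))  # 14.14
#' @export
rf_cv <- function(rf_values) {
  if (length(rf_values) < 2L) stop("need at least 2 response-factor values")
  m <- mean(rf_values)
  if (!is.finite(m) || m <= 0) stop("mean response factor must be > 0")
  100 * stats::sd(rf_values) / m
}

#' Relative standard error of repeated response factors
#'
#' `RSE% = 100 * (SD / sqrt(n)) / mean` over consecutive reanalyses of the
#' same working standard; the repeatability criterion of the instrument QC.
#'
#' @param repeat_values Numeric vector (>= 2 values, positive mean).
#' @return RSE in percent.
#' @export
rf_rse <- function(repeat_values) {
  rf_cv(repeat_values) / sqrt(length(repeat_values))
}

#' Fit the response-factor-versus-ECN model
#'
#' The core estimator for compounds lacking authentic standards: an ordinary
#' least-squares line `RF = slope * ECN + intercept` over the externally
#' calibrated standards. Predicted RFs then quantify every C/H/O compound
#' from its effective carbon number alone.
#'
#' @param standards A data.frame with columns `ecn` and `rf` (one row per
#'   calibration standard, >= 2 distinct ECN values); alternatively `ecn`
#'   and `rf` may be given as two numeric vectors via `rf`.
#' @param rf Optional numeric vector of response factors when `standards` is
#'   itself the numeric ECN vector.
#' @return An object of class `"rf_ecn"` with components `slope`,
#'   `intercept`, `r2`, `n_standards`, `fit` (the underlying `lm`) and
#'   `standards`.
#' @examples
#' mdl <- fit_rf_vs_ecn(data.frame(ecn = c(2, 4, 6), rf = c(85, 165, 245)))
#' predict(mdl, ecn = 3.62)
#' @export
fit_rf_vs_ecn <- function(standards, rf = NULL) {
  if (!is.null(rf)) standards <- data.frame(ecn = standards, rf = rf)
  standards <- as.data.frame(standards)
  if (!all(c("ecn", "rf") %in% names(standards)))
    stop("'standards' needs columns 'ecn' and 'rf'")
  standards <- standards[is.finite(standards$ecn) & is.finite(standards$rf), ,
                         drop = FALSE]
  if (nrow(standards) < 2L) stop("need at least 2 standards")
  if (length(unique(standards$ecn)) < 2L)
    stop("degenerate design: all ECN values identical")
  fit <- stats::lm(rf ~ ecn, data = standards)
  sm <- suppressWarnings(summary(fit))  # noise-free standards fit exactly
  structure(list(slope = unname(stats::coef(fit)["ecn"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r2 = sm$r.squared, n_standards = nrow(standards),
                 fit = fit, standards = standards),
            class = "rf_ecn")
}

#' @export
print.rf_ecn <- function(x, ...) {
  cat("Response-factor vs. effective-carbon-number model\n")
  cat(sprintf("  RF = %.4g * ECN %+.4g   (n = %d standards, R^2 = %.4f)\n",
              x$slope, x$intercept, x$n_standards, x$r2))
  invisible(x)
}

#' @export
summary.rf_ecn <- function(object, ...) {
  s <- summary(object$fit)
  cat("Response-factor vs. effective-carbon-number model\n\n")
  stats::printCoefmat(s$coefficients)
  cat(sprintf("\nn = %d standards, R^2 = %.4f, residual SD = %.4g\n",
              object$n_standards, object$r2, s$sigma))
  invisible(s)
}

#' @export
coef.rf_ecn <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.rf_ecn <- function(object, ...) stats::residuals(object$fit)

#' Predict response factors from ECN
#'
#' @param object A fitted [fit_rf_vs_ecn()] model.
#' @param ecn Numeric vector of effective carbon numbers.
#' @param ... Unused.
#' @return Predicted response factors (area per ng). A non-positive
#'   prediction is unphysical and raises an out-of-calibration-range error.
#' @export
predict.rf_ecn <- function(object, ecn, ...) {
  if (missing(ecn)) return(stats::fitted(object$fit))
  if (any(!is.finite(ecn))) stop("ecn must be finite")
  rf <- object$slope * ecn + object$intercept
  if (any(rf <= 0))
    stop(sprintf(
      "predicted response factor is not positive (ecn = %.4g -> rf = %.4g): outside the calibrated range",
      ecn[which(rf <= 0)[1]], rf[which(rf <= 0)[1]]))
  rf
}

#' @rdname predict.rf_ecn
#' @param model A fitted [fit_rf_vs_ecn()] model.
#' @export
predict_rf <- function(model, ecn) predict(model, ecn = ecn)

#' @export
plot.rf_ecn <- function(x, ...) {
  graphics::plot(x$standards$ecn, x$standards$rf,
                 xlab = "effective carbon number",
                 ylab = "response factor (area/ng)", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Convert a peak area to a headspace mass concentration
#'
#' `mass_ng = area / rf`; `concentration = mass_ng / sampled volume`,
#' reported in ug/m^3.
#'
#' @param area Peak area(s), >= 0.
#' @param rf Response factor(s) in area per ng, > 0.
#' @param geometry A [sampling_geometry()].
#' @return Concentration(s) in ug/m^3.
#' @examples
#' # 1 ng collected from 50 mL of headspace -> 20 ug/m^3
#' quantify(250, 250, sampling_geometry(50, 1))
#' @export
quantify <- function(area, rf, geometry = sampling_geometry()) {
  if (any(!is.finite(area)) || any(area < 0)) stop("area must be >= 0")
  if (any(!is.finite(rf)) || any(rf <= 0)) stop("rf must be > 0")
  if (!inherits(geometry, "sampling_geometry"))
    stop("'geometry' must be a sampling_geometry object")
  v <- geometry$sampled_volume_m3
  if (!is.finite(v) || v <= 0) stop("sampled volume must be > 0")
  mass_ng <- area / rf
  (mass_ng / 1000) / v   # ng -> ug, per m^3
}

#' Per-compound calibration table with QC statistics
#'
#' Fits one calibration curve per compound and batch/day, then summarises
#' response-factor stability across batches: mean RF, CV% across batches and
#' RSE% of the batch series. Mirrors the instrument-stability QC of a
#' multi-day storage experiment (CV and RSE expected below ~4%).
#'
#' @param calibration Long data.frame with columns `compound`, `batch_day`,
#'   `loading_ng`, `area`.
#' @param method Passed to [fit_calibration_curve()].
#' @return A data.frame: `compound`, `rf` (mean across batches), `r2`
#'   (worst batch), `cv_percent`, `rse_percent`, `n_batches`.
#' @export
calibration_table <- function(calibration,
                              method = c("zero_intercept", "mean_ratio")) {
  method <- match.arg(method)
  need <- setdiff(c("compound", "batch_day", "loading_ng", "area"),
                  names(calibration))
  if (length(need))
    stop("calibration table is missing column(s): ", paste(need, collapse = ", "))
  out <- lapply(split(calibration, calibration$compound), function(d) {
    fits <- lapply(split(d, d$batch_day), function(b)
      fit_calibration_curve(b$loading_ng, b$area, method = method,
                            compound = d$compound[1]))
    rfs <- vapply(fits, `[[`, numeric(1), "rf")
    data.frame(compound = d$compound[1],
               rf = mean(rfs),
               r2 = min(vapply(fits, `[[`, numeric(1), "r2")),
               cv_percent = if (length(rfs) >= 2) rf_cv(rfs) else NA_real_,
               rse_percent = if (length(rfs) >= 2) rf_rse(rfs) else NA_real_,
               n_batches = length(rfs))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
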