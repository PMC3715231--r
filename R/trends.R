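#' Simple linear trend fit
#'
#' Ordinary least squares of `y` on `x` packaged as a light S3 model object
#' carrying the quantities the profiling workflow reports: slope, intercept,
#' R^2 and the two-sided t-test p-value on the slope (reported for n >= 3).
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`, `x` not constant.
#' @return Object of class `"trend_fit"` with `slope`, `intercept`, `r2`,
#'   `p_value`, `n` and the underlying `fit`.
#' @examples
#' ols_fit(1:5, 2 * (1:5) + 1)  # slope 2, intercept 1, R^2 = 1
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 finite points")
  if (length(unique(x)) < 2L) stop("degenerate design: x is constant")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip the perfect-fit warning
  p <- if (length(x) >= 3L) unname(sm$coefficients["x", "Pr(>|t|)"])
       else NA_real_
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r2 = sm$r.squared, p_value = p, n = length(x), fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit: y = %.4g x %+.4g  (n = %d, R^2 = %.4f%s)\n",
              x$slope, x$intercept, x$n, x$r2,
              if (is.na(x$p_value)) ""
              else sprintf(", p = %.3g", x$p_value)))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.trend_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.trend_fit <- function(object, x, ...) {
  if (missing(x)) return(stats::fitted(object$fit))
  object$slope * x + object$intercept
}

#' @export
plot.trend_fit <- function(x, ...) {
  mf <- stats::model.frame(x$fit)
  graphics::plot(mf[[2]], mf[[1]], xlab = "x", ylab = "y", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

as_trend_row <- function(fit, scope, stat = NA_character_) {
  data.frame(scope = scope, stat = stat, slope = fit$slope,
             intercept = fit$intercept, r2 = fit$r2, p = fit$p_value,
             n = fit$n)
}

#' Regress log odor thresholds on molecular weight
#'
#' Odor thresholds of volatiles tend to fall with molecular weight; the
#' workflow quantifies that inverse relation as a linear fit of
#' `log10(threshold ppbv)` on MW, pooled over all threshold-bearing
#' compounds and/or within each functional group. The threshold statistic
#' (`max`, `min` or `geomean` over the literature replicates) is selectable;
#' groups with fewer than 3 threshold-bearing compounds are skipped with a
#' warning.
#'
#' @param registry Validated registry.
#' @param stat Threshold statistic, see [select_threshold()].
#' @param scope `"pooled"`, `"per_group"` or `"both"`.
#' @param exclude Optional character vector of compound names to drop before
#'   fitting (explicit outlier-trimming is user-supplied, never automated).
#' @return A list with `fits` (named list of `trend_fit`s, `"pooled"` and/or
#'   one per group) and `table` (one summary row per fit).
#' @export
threshold_mw_regression <- function(registry,
                                    stat = c("max", "min", "geomean"),
                                    scope = c("pooled", "per_group", "both"),
                                    exclude = NULL) {
  stat <- match.arg(stat)
  scope <- match.arg(scope)
  reg <- registry[registry$oav_eligible & !(registry$name %in% exclude), ,
                  drop = FALSE]
  if (nrow(reg) < 3L) stop("fewer than 3 threshold-bearing compounds")
  thr <- registry_thresholds(reg, stat)
  dat <- data.frame(mw = reg$mw, logt = log10(thr), group = reg$group)
  fits <- list()
  if (scope %in% c("pooled", "both"))
    fits$pooled <- ols_fit(dat$mw, dat$logt)
  if (scope %in% c("per_group", "both")) {
    for (g in unique(dat$group)) {
      d <- dat[dat$group == g, , drop = FALSE]
      if (nrow(d) < 3L) {
        warning("group '", g, "' has fewer than 3 threshold-bearing compounds; skipped")
        next
      }
      fits[[g]] <- ols_fit(d$mw, d$logt)
    }
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm)
    as_trend_row(fits[[nm]], scope = nm, stat = stat)))
  list(fits = fits, table = tab)
}

#' Log-linear odor-intensity trend over storage time
#'
#' Fits `log10(intensity)` against storage day — the decay law of the summed
#' odor activity or of the dilution-to-threshold sensory ratio over a
#' storage experiment.
#'
#' @param days Storage days.
#' @param intensity Positive intensity values (summed OAV, D/T ratio, ...).
#' @param transform Transformation applied before fitting (default `log10`).
#' @return A `trend_fit` of transformed intensity on day.
#' @export
intensity_trend <- function(days, intensity, transform = log10) {
  if (length(days) != length(intensity))
    stop("days and intensity must have the same length")
  bad <- which(!is.finite(intensity) | intensity <= 0)
  if (length(bad))
    stop("intensity must be > 0; offending day(s): ",
         paste(days[bad], collapse = ", "))
  ols_fit(days, transform(intensity))
}

#' Correlate summed odor activity with the sensory dilution-to-threshold ratio
#'
#' The dilution-to-threshold (D/T) ratio from an air-dilution sensory panel
#' is an instrument-free measure of odor intensity. This fit relates the
#' sensory measure to the chemical estimate on the log-log scale:
#' `log10(D/T) ~ log10(sum OAV)`, paired by sampling day, so a power-law
#' link `D/T = c * (sum OAV)^k` is recovered with slope `k`.
#'
#' @param oav_sums Data.frame `day`, `sum_oav` (e.g. from [sum_oav()]).
#' @param dt_ratios Data.frame `day`, `dt_ratio`.
#' @return A `trend_fit`.
#' @export
oav_dt_correlation <- function(oav_sums, dt_ratios) {
  if (!all(c("day", "sum_oav") %in% names(oav_sums)))
    stop("oav_sums needs columns day, sum_oav")
  if (!all(c("day", "dt_ratio") %in% names(dt_ratios)))
    stop("dt_ratios needs columns day, dt_ratio")
  if (!setequal(oav_sums$day, dt_ratios$day))
    stop("unpaired days between OAV sums and D/T ratios")
  m <- merge(oav_sums[c("day", "sum_oav")], dt_ratios[c("day", "dt_ratio")],
             by = "day")
  if (any(m$sum_oav <= 0) || any(m$dt_ratio <= 0))
    stop("OAV sums and D/T ratios must be > 0 for the log-log fit")
  ols_fit(log10(m$sum_oav), log10(m$dt_ratio))
}
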