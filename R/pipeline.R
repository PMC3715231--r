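#' Quantify a study from peak areas and external calibration
#'
#' The full semi-quantification pipeline: fit per-compound calibration
#' curves for the standards, regress their response factors on effective
#' carbon number, predict response factors for every C/H/O compound without
#' an authentic standard, and convert each peak area to a headspace
#' concentration through the sampling geometry. Compounds that are neither
#' directly calibrated nor ECN-eligible are reported with `NA`
#' concentrations — never silently extrapolated.
#'
#' @param areas Long data.frame `compound`, `day`, `area`.
#' @param calibration Long data.frame `compound`, `batch_day`, `loading_ng`,
#'   `area` for the authentic standards.
#' @param registry Validated registry (ECN column added if absent).
#' @param geometry A [sampling_geometry()].
#' @param molar_volume Molar volume (L/mol) for the ppbv conversion.
#' @param rf_method Calibration estimator, see [fit_calibration_curve()].
#' @param regression_scope `"global"` fits one RF-ECN line over all
#'   standards (default); `"per_group"` fits one per functional group
#'   (groups without >= 2 standards fall back to the global line).
#' @return A list: `concentrations` (long data.frame `compound`, `day`,
#'   `conc_ugm3`, `conc_ppb`, `rf`, `rf_source`), `calibration`
#'   (QC table from [calibration_table()]), `rf_model` (the fitted
#'   [fit_rf_vs_ecn()] model, or list of models for per-group scope).
#' @export
quantify_study <- function(areas, calibration, registry,
                           geometry = sampling_geometry(),
                           molar_volume = 24.5,
                           rf_method = c("zero_intercept", "mean_ratio"),
                           regression_scope = c("global", "per_group")) {
  rf_method <- match.arg(rf_method)
  regression_scope <- match.arg(regression_scope)
  need <- setdiff(c("compound", "day", "area"), names(areas))
  if (length(need))
    stop("areas table is missing column(s): ", paste(need, collapse = ", "))
  if (!"ecn" %in% names(registry)) registry <- add_ecn(registry)

  calib <- calibration_table(calibration, method = rf_method)
  idx <- match(calib$compound, registry$name)
  if (anyNA(idx))
    stop("calibrated compound(s) absent from registry: ",
         paste(calib$compound[is.na(idx)], collapse = ", "))
  std_ecn <- registry$ecn[idx]
  usable <- is.finite(std_ecn)
  if (sum(usable) < 2L)
    stop("need at least 2 ECN-eligible calibrated standards for the RF-ECN fit")
  global <- fit_rf_vs_ecn(data.frame(ecn = std_ecn[usable],
                                     rf = calib$rf[usable]))
  models <- list(global = global)
  if (regression_scope == "per_group") {
    grp <- registry$group[idx]
    for (g in unique(grp[usable])) {
      sel <- usable & grp == g
      if (sum(sel) >= 2L && length(unique(std_ecn[sel])) >= 2L)
        models[[g]] <- fit_rf_vs_ecn(data.frame(ecn = std_ecn[sel],
                                                rf = calib$rf[sel]))
    }
  }

  ridx <- match(areas$compound, registry$name)
  if (anyNA(ridx))
    stop("compound(s) absent from registry: ",
         paste(unique(areas$compound[is.na(ridx)]), collapse = ", "))
  direct_rf <- stats::setNames(calib$rf, calib$compound)
  rf <- rep(NA_real_, nrow(areas))
  src <- rep(NA_character_, nrow(areas))
  for (i in seq_len(nrow(areas))) {
    cp <- areas$compound[i]; j <- ridx[i]
    if (cp %in% names(direct_rf)) {
      rf[i] <- direct_rf[[cp]]; src[i] <- "standard"
    } else if (isTRUE(registry$ecn_eligible[j]) && is.finite(registry$ecn[j])) {
      mdl <- if (regression_scope == "per_group" &&
                 registry$group[j] %in% names(models))
        models[[registry$group[j]]] else models$global
      rf[i] <- predict(mdl, ecn = registry$ecn[j]); src[i] <- "ecn"
    }
  }
  conc_ugm3 <- ifelse(is.na(rf), NA_real_,
                      quantify(areas$area, ifelse(is.na(rf), 1, rf), geometry))
  conc_ppb <- ifelse(is.na(rf), NA_real_,
                     ugm3_to_ppb(conc_ugm3, registry$mw[ridx], molar_volume))
  skipped <- unique(areas$compound[is.na(rf)])
  if (length(skipped))
    warning("no response factor available (no standard, not ECN-eligible): ",
            paste(skipped, collapse = ", "))
  list(concentrations = data.frame(compound = areas$compound,
                                   day = areas$day, conc_ugm3 = conc_ugm3,
                                   conc_ppb = conc_ppb, rf = rf,
                                   rf_source = src),
       calibration = calib,
       rf_model = if (regression_scope == "global") global else models)
}
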