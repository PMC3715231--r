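#' Select a single odor threshold from literature replicates
#'
#' Literature odor thresholds for one compound often span orders of
#' magnitude. A selection policy collapses the replicates to one value:
#' `"max"` (the default, the most conservative odor-activity estimate and
#' the policy with the strongest threshold-molecular-weight correlation),
#' `"min"`, or `"geomean"`.
#'
#' @param t Numeric vector of thresholds in ppbv (all > 0). An empty vector
#'   signals OAV-ineligibility: a condition of class `aromaq_no_threshold`
#'   is raised as a warning and `NA` returned.
#' @param policy `"max"`, `"min"` or `"geomean"`.
#' @return Selected threshold in ppbv (or `NA` for an empty input).
#' @examples
#' select_threshold(c(1, 10, 100))            # 100
#' select_threshold(c(1, 10, 100), "geomean") # 10
#' @export
select_threshold <- function(t, policy = c("max", "min", "geomean")) {
  policy <- match.arg(policy)
  if (!length(t)) {
    w <- simpleWarning("no odor threshold available: compound is OAV-ineligible")
    class(w) <- c("aromaq_no_threshold", class(w))
    warning(w)
    return(NA_real_)
  }
  if (any(!is.finite(t)) || any(t <= 0)) stop("thresholds must be > 0")
  switch(policy,
         max = max(t),
         min = min(t),
         geomean = exp(mean(log(t))))
}

#' Odor activity value
#'
#' `OAV = concentration / threshold`, both in ppbv. An OAV above 1 marks a
#' compound whose headspace concentration exceeds its human detection
#' threshold.
#'
#' @param conc_ppb Concentration(s) in ppbv.
#' @param threshold Odor threshold(s) in ppbv, > 0.
#' @return Unitless OAV.
#' @export
compute_oav <- function(conc_ppb, threshold) {
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop("threshold must be > 0")
  conc_ppb / threshold
}

#' Build the odor-activity table
#'
#' Converts a concentration table into per-compound, per-day odor activity
#' values under a threshold-selection policy, and attaches relative
#' proportions (RP): a compound's percentage of the day's summed OAV over
#' the included compound set.
#'
#' Compounds without any literature threshold get `NA` OAV and are excluded
#' from every denominator (they stay in the output as a record). Entries
#' flagged below-detection are excluded by default — a non-detection has no
#' meaningful odor activity; `include_bdl = TRUE` lets the detection-limit
#' placeholder contribute instead.
#'
#' @param conc Long table with `compound`, `day` and `conc_ppb` (if only
#'   `conc_ugm3` is present it is converted through the registry molecular
#'   weight).
#' @param registry Validated registry carrying thresholds, groups and MWs.
#' @param policy Threshold-selection policy, see [select_threshold()].
#' @param include_bdl Let below-detection placeholders contribute to OAV?
#' @param molar_volume Molar volume for any needed unit conversion.
#' @return Data.frame of class `c("oav_table", "data.frame")`: `compound`,
#'   `group`, `day`, `oav`, `rp`.
#' @export
oav_table <- function(conc, registry, policy = c("max", "min", "geomean"),
                      include_bdl = FALSE, molar_volume = 24.5) {
  policy <- match.arg(policy)
  idx <- match(conc$compound, registry$name)
  if (anyNA(idx))
    stop("compound(s) absent from registry: ",
         paste(unique(conc$compound[is.na(idx)]), collapse = ", "))
  if (!"conc_ppb" %in% names(conc)) {
    if (!"conc_ugm3" %in% names(conc))
      stop("need a 'conc_ppb' or 'conc_ugm3' column")
    conc$conc_ppb <- ugm3_to_ppb(conc$conc_ugm3, registry$mw[idx],
                                 molar_volume)
  }
  thr <- registry_thresholds(registry, policy)[idx]
  skipped <- unique(conc$compound[is.na(thr)])
  if (length(skipped))
    warning("no odor threshold for: ", paste(skipped, collapse = ", "),
            " (reported with NA OAV)")
  bdl <- if ("bdl" %in% names(conc)) conc$bdl else rep(FALSE, nrow(conc))
  oav <- ifelse(is.na(thr) | (bdl & !include_bdl), NA_real_,
                conc$conc_ppb / thr)
  out <- data.frame(compound = conc$compound, group = registry$group[idx],
                    day = conc$day, oav = oav)
  out$rp <- NA_real_
  for (d in unique(out$day)) {
    sel <- out$day == d
    s <- sum(out$oav[sel], na.rm = TRUE)
    if (s > 0) out$rp[sel] <- 100 * out$oav[sel] / s
  }
  class(out) <- c("oav_table", "data.frame")
  out
}

#' Relative proportion of OAV for one day
#'
#' `RP = 100 * OAV / sum(OAV)` over the included compound set at that day.
#'
#' @param oav_tab An [oav_table()].
#' @param day Sampling day to profile.
#' @return Data.frame `compound`, `group`, `oav`, `rp`, sorted by
#'   decreasing RP.
#' @export
relative_proportion <- function(oav_tab, day) {
  sel <- oav_tab$day == day
  if (!any(sel)) stop("day ", day, " not present in the OAV table")
  s <- sum(oav_tab$oav[sel], na.rm = TRUE)
  if (s <= 0) stop("summed OAV is zero at day ", day)
  out <- oav_tab[sel, c("compound", "group", "oav", "rp")]
  out[order(-ifelse(is.na(out$rp), -Inf, out$rp)), , drop = FALSE]
}

#' Summed odor activity
#'
#' Arithmetic sum of OAV over all compounds or per functional group,
#' per day.
#'
#' @param oav_tab An [oav_table()].
#' @param scope `"all"` or `"group"`.
#' @param day Optional day filter (default: every day in the table).
#' @return Data.frame `day`, `sum_oav` (plus `group` for scope "group").
#' @export
sum_oav <- function(oav_tab, scope = c("all", "group"), day = NULL) {
  scope <- match.arg(scope)
  tab <- if (is.null(day)) oav_tab else oav_tab[oav_tab$day %in% day, ,
                                                drop = FALSE]
  if (scope == "all") {
    out <- stats::aggregate(oav ~ day, data = tab, FUN = sum, na.rm = TRUE,
                            na.action = stats::na.pass)
    names(out)[2] <- "sum_oav"
  } else {
    out <- stats::aggregate(oav ~ group + day, data = tab, FUN = sum,
                            na.rm = TRUE, na.action = stats::na.pass)
    names(out)[3] <- "sum_oav"
  }
  out
}

#' Aggregate odor activity over a storage period
#'
#' Sums each compound's OAV over a set of sampling days (for example the
#' "fresh" period of a storage experiment) and reports, for an optional
#' compound subset, the subset's share of the all-compound period total:
#' `subset RP = 100 * sum(subset OAV) / sum(all OAV)` over those days.
#'
#' @param oav_tab An [oav_table()].
#' @param days Subset of sampled days to aggregate over.
#' @param compounds Optional character vector naming the subset of interest.
#' @return A list with `per_compound` (data.frame `compound`, `sum_oav`,
#'   sorted decreasing), `total_oav` (all-compound period total) and
#'   `subset_rp` (percent, `NA` when no subset was given).
#' @export
period_aggregate <- function(oav_tab, days, compounds = NULL) {
  missing_days <- setdiff(days, unique(oav_tab$day))
  if (length(missing_days))
    stop("day(s) not in the OAV table: ", paste(missing_days, collapse = ", "))
  tab <- oav_tab[oav_tab$day %in% days, , drop = FALSE]
  per <- stats::aggregate(oav ~ compound, data = tab, FUN = sum, na.rm = TRUE,
                          na.action = stats::na.pass)
  names(per)[2] <- "sum_oav"
  per <- per[order(-per$sum_oav), , drop = FALSE]
  rownames(per) <- NULL
  total <- sum(tab$oav, na.rm = TRUE)
  subset_rp <- NA_real_
  if (!is.null(compounds)) {
    absent <- setdiff(compounds, per$compound)
    if (length(absent))
      stop("compound(s) not in the OAV table: ", paste(absent, collapse = ", "))
    if (total <= 0) stop("all-compound period OAV total is zero")
    subset_rp <- 100 * sum(per$sum_oav[per$compound %in% compounds]) / total
  }
  list(per_compound = per, total_oav = total, subset_rp = subset_rp)
}
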