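#' Apply method detection limits to a concentration table
#'
#' Entries measured below their compound's method detection limit (MDL) are
#' flagged `bdl` and carry the MDL itself as the stored value — the reporting
#' convention of the storage-study tables, where below-detection cells hold
#' the detection limit rather than zero.
#'
#' @param conc Long concentration table: columns `compound`, `day` and at
#'   least one of `conc_ppb` / `conc_ugm3`.
#' @param mdl Named numeric vector of detection limits (same unit as `unit`),
#'   one per measured compound, all > 0.
#' @param unit Which column the MDL refers to: `"conc_ppb"` or `"conc_ugm3"`.
#' @return `conc` with the flagged values replaced by the MDL, a logical
#'   `bdl` column, and an `mdl_value` column.
#' @export
apply_mdl <- function(conc, mdl, unit = c("conc_ppb", "conc_ugm3")) {
  unit <- match.arg(unit)
  if (!unit %in% names(conc)) stop("column '", unit, "' not found")
  if (is.null(names(mdl)) || any(!nzchar(names(mdl))))
    stop("'mdl' must be a named vector of per-compound detection limits")
  if (any(!is.finite(mdl)) || any(mdl <= 0)) stop("all MDL values must be > 0")
  missing <- setdiff(unique(conc$compound), names(mdl))
  if (length(missing))
    stop("no MDL given for measured compound(s): ",
         paste(missing, collapse = ", "))
  lim <- mdl[conc$compound]
  v <- conc[[unit]]
  flag <- v < lim
  v[flag] <- lim[flag]
  conc[[unit]] <- v
  conc$bdl <- flag
  conc$mdl_value <- unname(lim)
  conc
}

merge_group <- function(conc, registry) {
  if (!"group" %in% names(conc)) {
    if (is.null(registry))
      stop("concentration table has no 'group' column; supply a registry")
    idx <- match(conc$compound, registry$name)
    if (anyNA(idx))
      stop("compound(s) absent from registry: ",
           paste(unique(conc$compound[is.na(idx)]), collapse = ", "))
    conc$group <- registry$group[idx]
  }
  conc
}

#' Per-group, per-day summed concentrations and detection counts
#'
#' Reproduces the group-summary layout of a storage experiment: for every
#' functional group and sampling day, the number of detected compounds, the
#' number also detected at the immediately preceding sampled day, and the
#' summed mass concentration in ug/m^3. "Detected" means not flagged
#' below-detection; by default the below-detection placeholder values are
#' excluded from the sums as well (the convention of the published summed
#' rows), but `include_bdl = TRUE` adds them.
#'
#' @param conc Long table with `compound`, `day`, `conc_ugm3` and (optionally)
#'   `bdl` and `group`.
#' @param registry Registry supplying `group` when `conc` lacks it.
#' @param include_bdl Include below-detection placeholder values in the sums?
#' @return Data.frame: `group`, `day`, `n_detected`, `n_consistent`,
#'   `sum_ugm3`.
#' @export
group_sums <- function(conc, registry = NULL, include_bdl = FALSE) {
  conc <- merge_group(conc, registry)
  if (!"bdl" %in% names(conc)) conc$bdl <- FALSE
  if (!"conc_ugm3" %in% names(conc)) stop("column 'conc_ugm3' required")
  days <- sort(unique(conc$day))
  cons <- consistency_counts(conc, registry)
  out <- expand.grid(group = sort(unique(conc$group)), day = days,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$n_detected <- mapply(function(g, d) {
    sum(conc$group == g & conc$day == d & !conc$bdl)
  }, out$group, out$day)
  out$n_consistent <- cons$n_consistent[match(paste(out$group, out$day),
                                              paste(cons$group, cons$day))]
  out$sum_ugm3 <- mapply(function(g, d) {
    sel <- conc$group == g & conc$day == d & (include_bdl | !conc$bdl)
    sum(conc$conc_ugm3[sel])
  }, out$group, out$day)
  out[order(out$group, out$day), , drop = FALSE]
}

#' Count compounds detected consistently from the previous sampled day
#'
#' For every group and every day after the first, the number of detected
#' compounds that were also detected at the immediately preceding *sampled*
#' day (the day grid need not be consecutive calendar days).
#'
#' @inheritParams group_sums
#' @return Data.frame `group`, `day`, `n_consistent` (NA for the first day).
#' @export
consistency_counts <- function(conc, registry = NULL) {
  conc <- merge_group(conc, registry)
  if (!"bdl" %in% names(conc)) conc$bdl <- FALSE
  days <- sort(unique(conc$day))
  groups <- sort(unique(conc$group))
  detected <- function(g, d) unique(conc$compound[conc$group == g &
                                                  conc$day == d & !conc$bdl])
  out <- expand.grid(group = groups, day = days, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$n_consistent <- mapply(function(g, d) {
    i <- match(d, days)
    if (i == 1L) return(NA_integer_)
    length(intersect(detected(g, d), detected(g, days[i - 1L])))
  }, out$group, out$day)
  out[order(out$group, out$day), , drop = FALSE]
}

#' Relative composition (RC) of each compound per day
#'
#' RC is a compound's percentage of the day's total mass concentration:
#' `RC = 100 * conc_ugm3 / total(day)`. The totals are supplied externally
#' because the day totals of a full study typically cover more compounds
#' than a printed major-compound table; the RC of any subset therefore sums
#' to at most 100.
#'
#' @param conc Long table with `compound`, `day`, `conc_ugm3`.
#' @param total_per_day Named numeric vector (names = days) or data.frame
#'   with columns `day` and `sum_ugm3`/`total_ugm3`, all totals > 0.
#' @return `conc` with an `rc` column (percent).
#' @export
relative_composition <- function(conc, total_per_day) {
  if (is.data.frame(total_per_day)) {
    vcol <- intersect(c("total_ugm3", "sum_ugm3"), names(total_per_day))[1]
    if (is.na(vcol) || !"day" %in% names(total_per_day))
      stop("total_per_day needs columns 'day' and 'sum_ugm3' (or 'total_ugm3')")
    totals <- stats::setNames(total_per_day[[vcol]], total_per_day$day)
  } else {
    totals <- total_per_day
  }
  idx <- match(as.character(conc$day), names(totals))
  if (anyNA(idx))
    stop("no total given for day(s): ",
         paste(unique(conc$day[is.na(idx)]), collapse = ", "))
  tot <- as.numeric(totals)[idx]
  if (any(tot <= 0)) stop("all per-day totals must be > 0")
  conc$rc <- 100 * conc$conc_ugm3 / tot
  conc
}

#' Select major compounds by relative composition
#'
#' A compound is "major" if its RC exceeds the cutoff on at least one
#' sampling day. The default cutoff of 0.05 percent is the selection rule of
#' the storage study, which reduces 147 detected volatiles to 53 majors.
#'
#' @param rc_table Output of [relative_composition()] (columns `compound`,
#'   `day`, `rc`).
#' @param cutoff RC cutoff in percent (> 0).
#' @return Data.frame `compound`, `max_rc`, `qualifying_days` (the days on
#'   which RC exceeded the cutoff, as a comma-separated string).
#' @export
select_major <- function(rc_table, cutoff = 0.05) {
  if (!all(c("compound", "day", "rc") %in% names(rc_table)))
    stop("rc_table needs columns compound, day, rc")
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  res <- lapply(split(rc_table, rc_table$compound), function(d) {
    qd <- d$day[d$rc > cutoff]
    if (!length(qd)) return(NULL)
    data.frame(compound = d$compound[1], max_rc = max(d$rc),
               qualifying_days = paste(sort(qd), collapse = ","))
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(compound = character(0), max_rc = numeric(0),
                      qualifying_days = character(0)))
  rownames(res) <- NULL
  res[order(-res$max_rc), , drop = FALSE]
}
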