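#' Read a compound registry CSV
#'
#' Expected columns: `name`, `formula`, `mw`, `group`, `n_C`, `n_H`, `n_O`,
#' `n_carbonyl`, `n_ether`, `n_methyl`, `thresholds` (semicolon-separated
#' `value@source` entries in ppbv), `descriptors`, `is_standard`.
#'
#' @param path CSV file path.
#' @return A validated registry, see [validate_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  validate_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a long concentration CSV
#'
#' Expected columns: `compound`, `day`, and `conc_ppb` and/or `conc_ugm3`;
#' optional `bdl` logical flag.
#'
#' @param path CSV file path.
#' @return Data.frame.
#' @export
read_concentrations <- function(path) {
  if (!file.exists(path)) stop("concentration file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("compound", "day"), names(df))
  if (length(need))
    stop("concentration file missing column(s): ", paste(need, collapse = ", "))
  if (!any(c("conc_ppb", "conc_ugm3") %in% names(df)))
    stop("concentration file needs a conc_ppb or conc_ugm3 column")
  if (nrow(df) == 0L) stop("concentration file is empty: ", path)
  df
}

#' Read an external-calibration CSV
#'
#' Expected columns: `compound`, `batch_day`, `loading_ng`, `area`.
#'
#' @param path CSV file path.
#' @return Data.frame.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("compound", "batch_day", "loading_ng", "area"), names(df))
  if (length(need))
    stop("calibration file missing column(s): ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("calibration file is empty: ", path)
  df
}

#' Read a dilution-to-threshold CSV
#'
#' Expected columns: `day`, `dt_ratio`.
#'
#' @param path CSV file path.
#' @return Data.frame.
#' @export
read_dt <- function(path) {
  if (!file.exists(path)) stop("D/T file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("day", "dt_ratio"), names(df))
  if (length(need))
    stop("D/T file missing column(s): ", paste(need, collapse = ", "))
  df
}

#' Packaged strawberry storage-study tables
#'
#' Loaders for the worked data set shipped with the package: the published
#' summary tables of a nine-day strawberry storage experiment, transcribed
#' to CSV.
#'
#' * `strawberry_registry()` — the 53 major volatiles (relative composition
#'   > 0.05 % on at least one day) with formulas, molecular weights,
#'   functional groups, ECN moiety counts and odor thresholds. The
#'   thresholds are *back-solved* from the published concentration and
#'   odor-activity values (threshold = concentration / OAV); the original
#'   literature survey behind them is not public, so these are derived
#'   working values, not the surveyed records.
#' * `strawberry_concentrations()` — compound x storage-day concentrations
#'   in both ppbv and ug/m^3 with below-detection flags (below-detection
#'   cells hold the method detection limit, the source's convention).
#' * `strawberry_group_summary()` — per functional group and day: number of
#'   detected compounds (over the full 147-compound study, not only the 53
#'   majors), number also detected at the previous sampled day, and summed
#'   concentration; the `all` rows carry the study-wide totals used as
#'   relative-composition denominators.
#' * `strawberry_oav_printed()` — the published per-compound odor activity
#'   values and relative proportions, kept as an expected-values reference
#'   (blank cells of the source are `NA`).
#'
#' @return A data.frame (a validated registry for
#'   `strawberry_registry()`).
#' @examples
#' reg <- strawberry_registry()
#' conc <- strawberry_concentrations()
#' head(conc)
#' @export
strawberry_registry <- function() {
  read_registry(system.file("extdata", "strawberry_registry.csv",
                            package = "aromaq", mustWork = TRUE))
}

#' @rdname strawberry_registry
#' @export
strawberry_concentrations <- function() {
  read_concentrations(system.file("extdata", "strawberry_concentrations.csv",
                                  package = "aromaq", mustWork = TRUE))
}

#' @rdname strawberry_registry
#' @export
strawberry_group_summary <- function() {
  utils::read.csv(system.file("extdata", "strawberry_group_summary.csv",
                              package = "aromaq", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname strawberry_registry
#' @export
strawberry_oav_printed <- function() {
  utils::read.csv(system.file("extdata", "strawberry_oav_printed.csv",
                              package = "aromaq", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Run configuration for the driver functions
#'
#' @param registry,areas,calibration,concentrations,dt Input CSV paths
#'   (whichever the driver needs).
#' @param out_dir Output directory (created if missing).
#' @param molar_volume Molar volume in L/mol.
#' @param threshold_policy Threshold-selection policy.
#' @param rc_cutoff Major-compound RC cutoff in percent.
#' @param include_bdl Include below-detection placeholders in sums / OAV.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `"aromaq_config"`.
#' @export
aromaq_config <- function(registry = NULL, areas = NULL, calibration = NULL,
                          concentrations = NULL, dt = NULL,
                          out_dir = tempfile("aromaq_"),
                          molar_volume = 24.5, threshold_policy = "max",
                          rc_cutoff = 0.05, include_bdl = FALSE,
                          seed = 1L) {
  if (rc_cutoff <= 0) stop("rc_cutoff must be > 0")
  structure(list(registry = registry, areas = areas,
                 calibration = calibration, concentrations = concentrations,
                 dt = dt, out_dir = out_dir, molar_volume = molar_volume,
                 threshold_policy = threshold_policy, rc_cutoff = rc_cutoff,
                 include_bdl = include_bdl, seed = as.integer(seed)),
            class = "aromaq_config")
}

write_manifest <- function(config, out_dir) {
  inputs <- Filter(Negate(is.null),
                   config[c("registry", "areas", "calibration",
                            "concentrations", "dt")])
  man <- data.frame(input = names(inputs),
                    path = unlist(inputs),
                    md5 = vapply(unlist(inputs),
                                 function(p) unname(tools::md5sum(p)), ""),
                    row.names = NULL)
  man$seed <- config$seed
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(man)
}

#' Quantification driver: areas + calibration -> concentration table
#'
#' Reads the registry, calibration and peak-area CSVs named in the config,
#' runs [quantify_study()], writes `concentrations.csv`,
#' `calibration_report.csv` and a `manifest.csv` of input hashes to the
#' output directory, and logs QC warnings for calibration batches with
#' CV above 4 % or R^2 below 0.99.
#'
#' @param config An [aromaq_config()] with `registry`, `areas` and
#'   `calibration` paths set.
#' @return Invisibly, the [quantify_study()] result.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "aromaq_config"))
  for (f in c("registry", "areas", "calibration"))
    if (is.null(config[[f]]))
      stop("config is missing the '", f, "' input path")
  registry <- read_registry(config$registry)
  areas <- read_concentrations_like(config$areas, value = "area")
  calibration <- read_calibration(config$calibration)
  res <- quantify_study(areas, calibration, registry,
                        molar_volume = config$molar_volume)
  bad <- res$calibration[!is.na(res$calibration$cv_percent) &
                           (res$calibration$cv_percent > 4 |
                            res$calibration$r2 < 0.99), , drop = FALSE]
  for (i in seq_len(nrow(bad)))
    warning(sprintf("calibration QC: %s has CV %.2f%% / min R^2 %.4f",
                    bad$compound[i], bad$cv_percent[i], bad$r2[i]))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$concentrations,
                   file.path(config$out_dir, "concentrations.csv"),
                   row.names = FALSE)
  utils::write.csv(res$calibration,
                   file.path(config$out_dir, "calibration_report.csv"),
                   row.names = FALSE)
  write_manifest(config, config$out_dir)
  invisible(res)
}

read_concentrations_like <- function(path, value = "area") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("compound", "day", value), names(df))
  if (length(need))
    stop("file '", path, "' missing column(s): ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("input file is empty: ", path)
  df
}

#' Profiling driver: concentrations -> RC / OAV / trend reports
#'
#' Reads a concentration table and the registry, then writes the profiling
#' reports to the output directory: `group_sums.csv`,
#' `relative_composition.csv`, `major_compounds.csv`, and — when the
#' registry carries thresholds — `oav.csv` and `oav_sums.csv` plus a
#' `trend_fits.csv` with the log-intensity storage trend (and the
#' OAV-versus-D/T fit when a D/T file is configured). If no compound has a
#' threshold the OAV stage is skipped with a warning and the RC outputs are
#' still produced.
#'
#' @param config An [aromaq_config()] with `registry` and `concentrations`
#'   set; optional `dt`.
#' @param total_per_day Optional named day-total vector for RC denominators;
#'   defaults to the per-day sums of the input table itself.
#' @return Invisibly, a list of the computed tables.
#' @export
run_profile <- function(config, total_per_day = NULL) {
  stopifnot(inherits(config, "aromaq_config"))
  for (f in c("registry", "concentrations"))
    if (is.null(config[[f]]))
      stop("config is missing the '", f, "' input path")
  registry <- read_registry(config$registry)
  conc <- read_concentrations(config$concentrations)
  if (!"conc_ugm3" %in% names(conc)) {
    idx <- match(conc$compound, registry$name)
    conc$conc_ugm3 <- ppb_to_ugm3(conc$conc_ppb, registry$mw[idx],
                                  config$molar_volume)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  gs <- group_sums(conc, registry, include_bdl = config$include_bdl)
  if (is.null(total_per_day)) {
    tot <- stats::aggregate(conc_ugm3 ~ day, data = conc, FUN = sum)
    total_per_day <- stats::setNames(tot$conc_ugm3, tot$day)
  }
  rc <- relative_composition(conc, total_per_day)
  majors <- select_major(rc, cutoff = config$rc_cutoff)
  utils::write.csv(gs, file.path(config$out_dir, "group_sums.csv"),
                   row.names = FALSE)
  utils::write.csv(rc, file.path(config$out_dir, "relative_composition.csv"),
                   row.names = FALSE)
  utils::write.csv(majors, file.path(config$out_dir, "major_compounds.csv"),
                   row.names = FALSE)

  out <- list(group_sums = gs, relative_composition = rc, majors = majors)
  if (any(registry$oav_eligible)) {
    oav <- oav_table(conc, registry, policy = config$threshold_policy,
                     include_bdl = config$include_bdl,
                     molar_volume = config$molar_volume)
    sums <- sum_oav(oav)
    utils::write.csv(oav, file.path(config$out_dir, "oav.csv"),
                     row.names = FALSE)
    utils::write.csv(sums, file.path(config$out_dir, "oav_sums.csv"),
                     row.names = FALSE)
    fits <- list()
    if (all(sums$sum_oav > 0) && nrow(sums) >= 2L)
      fits$log_sum_oav_vs_day <- intensity_trend(sums$day, sums$sum_oav)
    if (!is.null(config$dt)) {
      dt <- read_dt(config$dt)
      fits$log_sum_oav_vs_log_dt <- oav_dt_correlation(sums, dt)
    }
    if (length(fits)) {
      ft <- do.call(rbind, lapply(names(fits), function(nm)
        as_trend_row(fits[[nm]], scope = nm)))
      utils::write.csv(ft, file.path(config$out_dir, "trend_fits.csv"),
                       row.names = FALSE)
    }
    out <- c(out, list(oav = oav, oav_sums = sums, trends = fits))
  } else {
    warning("no compound carries an odor threshold; OAV stage skipped")
  }
  write_manifest(config, config$out_dir)
  invisible(out)
}
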