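#' Define a synthetic storage-study scenario
#'
#' Bundles every knob of the seeded generators that emulate a fruit-storage
#' headspace experiment: functional-group census, sampling-day grid, the
#' fresh-to-decay concentration dynamics (esters surge to a peak early and
#' collapse once decay starts; alcohols peak during decay), multiplicative
#' lognormal measurement noise on peak areas, the generating response-factor
#' versus ECN line, the scatter of literature odor thresholds, and the
#' power-law link between summed odor activity and the sensory
#' dilution-to-threshold ratio.
#'
#' @param n_per_group Named integer vector: compounds per functional group.
#' @param days Strictly increasing sampling-day grid.
#' @param noise_sigma Lognormal sigma of the multiplicative area noise.
#' @param rf_slope,rf_intercept Generating RF = slope * ECN + intercept line.
#' @param threshold_sigma Log10-scale SD among literature threshold
#'   replicates.
#' @param threshold_mw_slope Generating slope of log10(threshold) on MW
#'   (negative: heavier compounds smell stronger).
#' @param dt_exponent,dt_scale Power law `D/T = scale * (sum OAV)^exponent`.
#' @param n_standards Number of compounds granted authentic calibration
#'   standards.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `"study_scenario"`.
#' @export
study_scenario <- function(n_per_group = c(ester = 23, alcohol = 11,
                                           aldehyde = 5, ketone = 5,
                                           fatty_acid = 2, etc = 7),
                           days = c(0, 1, 3, 6, 9),
                           noise_sigma = 0.02,
                           rf_slope = 40, rf_intercept = 5,
                           threshold_sigma = 0.5,
                           threshold_mw_slope = -0.02,
                           dt_exponent = 0.5, dt_scale = 1,
                           n_standards = 19, seed = 1L) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% .vocs_groups))
    stop("n_per_group must be named by functional group")
  if (any(n_per_group < 0)) stop("n_per_group must be >= 0")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (noise_sigma < 0 || threshold_sigma < 0) stop("noise scales must be >= 0")
  if (rf_slope <= 0 || rf_intercept <= 0 || dt_scale <= 0)
    stop("rf_slope, rf_intercept and dt_scale must be > 0")
  if (n_standards < 2) stop("need at least 2 standards")
  structure(list(n_per_group = n_per_group, days = days,
                 noise_sigma = noise_sigma, rf_slope = rf_slope,
                 rf_intercept = rf_intercept,
                 threshold_sigma = threshold_sigma,
                 threshold_mw_slope = threshold_mw_slope,
                 dt_exponent = dt_exponent, dt_scale = dt_scale,
                 n_standards = n_standards, seed = as.integer(seed)),
            class = "study_scenario")
}

# Group concentration dynamics, relative to the day-0 level. Anchors follow
# the canonical storage-study pattern: esters surge ~13x by day 3 then
# collapse >1000x with decay; alcohols climb ~3 orders of magnitude to a
# day-6 peak; the remaining classes fade. Log-linear interpolation between
# anchor days, clamped outside the grid.
.profile_anchors <- list(
  ester      = c("0" = 1,    "1" = 0.81, "3" = 13.4,  "6" = 1.0e-2, "9" = 8.7e-4),
  alcohol    = c("0" = 1,    "1" = 2.6,  "3" = 7.7,   "6" = 2713,   "9" = 33),
  aldehyde   = c("0" = 1,    "1" = 1.01, "3" = 6.5,   "6" = 0.46,   "9" = 0.35),
  ketone     = c("0" = 1,    "1" = 1.22, "3" = 0.094, "6" = 5.6e-3, "9" = 1.2e-2),
  fatty_acid = c("0" = 1,    "1" = 0.74, "3" = 0.68,  "6" = 8.1e-2, "9" = 3.3e-2),
  etc        = c("0" = 1,    "1" = 0.52, "3" = 0.48,  "6" = 0.16,   "9" = 0.33))

group_profile <- function(group, day) {
  a <- .profile_anchors[[group]]
  ad <- as.numeric(names(a))
  10^stats::approx(ad, log10(a), xout = pmin(pmax(day, min(ad)), max(ad)))$y
}

# Geometric-mean day-0 concentration (ug/m^3) per group; alcohols start low
# and surge later, esters dominate the fresh profile.
.base_level <- c(ester = 500, alcohol = 12, aldehyde = 300, ketone = 400,
                 fatty_acid = 1000, etc = 15)
# log10 threshold intercepts per group (at MW = 0)
.thr_intercept <- c(ester = 1.8, alcohol = 2.8, aldehyde = 2.2, ketone = 3.2,
                    fatty_acid = 2.4, etc = 3.6)

#' Generate a synthetic compound registry
#'
#' Draws plausible C/H/O molecules per functional class (saturated skeleta
#' with class-typical moieties), with molecular weights consistent with the
#' formula and 1-4 literature-style odor thresholds per compound scattered
#' lognormally around a class mean that decreases with molecular weight.
#' `n_standards` compounds, spread evenly across the ECN range, are marked
#' as having authentic calibration standards.
#'
#' @param scenario A [study_scenario()].
#' @return A validated registry (see [validate_registry()]).
#' @export
generate_registry <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  set.seed(scenario$seed)
  rows <- list()
  for (g in names(scenario$n_per_group)) {
    n <- scenario$n_per_group[[g]]
    if (n == 0) next
    for (i in seq_len(n)) {
      nc <- switch(g,
        ester = sample(3:9, 1), alcohol = sample(2:8, 1),
        aldehyde = sample(2:7, 1), ketone = sample(3:7, 1),
        fatty_acid = sample(2:6, 1), etc = sample(4:10, 1))
      spec <- switch(g,
        ester      = list(H = 2 * nc,     O = 2L, cb = 1L, et = 1L, me = 2L),
        alcohol    = list(H = 2 * nc + 2, O = 1L, cb = 0L, et = 0L, me = 1L),
        aldehyde   = list(H = 2 * nc,     O = 1L, cb = 1L, et = 0L, me = 1L),
        ketone     = list(H = 2 * nc,     O = 1L, cb = 1L, et = 0L, me = 2L),
        fatty_acid = list(H = 2 * nc,     O = 2L, cb = 1L, et = 0L, me = 1L),
        etc        = list(H = 2 * nc + 2, O = 0L, cb = 0L, et = 0L, me = 2L))
      formula <- compose_formula(nc, spec$H, spec$O)
      mw <- formula_mw(formula)
      n_thr <- sample(1:4, 1)
      logt <- .thr_intercept[[g]] + scenario$threshold_mw_slope * mw +
        stats::rnorm(n_thr, 0, scenario$threshold_sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s_%02d", g, i), formula = formula, mw = mw,
        group = g, n_C = nc, n_H = spec$H, n_O = spec$O,
        n_carbonyl = spec$cb, n_ether = spec$et, n_methyl = spec$me,
        thresholds = paste0(signif(10^logt, 6), "@synthetic",
                            collapse = ";"),
        descriptors = "", is_standard = FALSE)
    }
  }
  reg <- validate_registry(do.call(rbind, rows))
  reg <- add_ecn(reg)
  # standards spread evenly over the ECN range for a well-conditioned fit
  ord <- order(reg$ecn)
  k <- min(scenario$n_standards, nrow(reg))
  pick <- ord[unique(round(seq(1, nrow(reg), length.out = k)))]
  reg$is_standard[pick] <- TRUE
  reg
}

#' Generate a synthetic storage study
#'
#' Builds the ground-truth concentration trajectories (group dynamics times
#' a compound-specific lognormal base level), the observed peak areas
#' (truth x generating response factor x multiplicative lognormal noise)
#' and the per-batch external calibration data for the standards. With
#' `noise_sigma = 0` the observations are an exact deterministic image of
#' the truth, so the full quantification pipeline must recover it exactly.
#'
#' @param scenario A [study_scenario()].
#' @param registry Registry from [generate_registry()] (regenerated from the
#'   scenario when omitted).
#' @param geometry A [sampling_geometry()].
#' @return A list of class `"synthetic_study"`: `registry`, `truth` (long
#'   data.frame `compound`, `day`, `conc_ugm3`, `conc_ppb`, `bdl`), `areas`
#'   (`compound`, `day`, `area`), `calibration` (`compound`, `batch_day`,
#'   `loading_ng`, `area`), `rf_true` (named vector) and `geometry`.
#' @export
generate_study <- function(scenario, registry = generate_registry(scenario),
                           geometry = sampling_geometry()) {
  stopifnot(inherits(scenario, "study_scenario"))
  set.seed(scenario$seed + 1L)
  if (!"ecn" %in% names(registry)) registry <- add_ecn(registry)
  rf_true <- scenario$rf_slope * registry$ecn + scenario$rf_intercept
  if (any(rf_true <= 0, na.rm = TRUE))
    stop("generating RF line produces non-positive response factors")
  names(rf_true) <- registry$name
  base <- .base_level[registry$group] *
    stats::rlnorm(nrow(registry), 0, 1.2)
  days <- scenario$days
  noise <- function(n) stats::rlnorm(n, 0, scenario$noise_sigma)

  truth <- do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
    conc <- base[i] * group_profile(registry$group[i], days)
    data.frame(compound = registry$name[i], day = days, conc_ugm3 = conc,
               conc_ppb = ugm3_to_ppb(conc, registry$mw[i]), bdl = FALSE)
  }))
  mass_ng <- truth$conc_ugm3 * geometry$sampled_volume_m3 * 1000
  areas <- data.frame(compound = truth$compound, day = truth$day,
                      area = mass_ng * rf_true[truth$compound] *
                        noise(nrow(truth)))

  std <- registry$name[registry$is_standard]
  loadings <- c(1.30, 6.52, 13.0, 26.1, 65.2)
  calibration <- do.call(rbind, lapply(std, function(cp) {
    do.call(rbind, lapply(days, function(d) {
      data.frame(compound = cp, batch_day = d, loading_ng = loadings,
                 area = loadings * rf_true[cp] * noise(length(loadings)))
    }))
  }))
  structure(list(registry = registry, truth = truth, areas = areas,
                 calibration = calibration, rf_true = rf_true,
                 geometry = geometry, scenario = scenario),
            class = "synthetic_study")
}

#' Generate sensory dilution-to-threshold ratios from summed odor activity
#'
#' `D/T = dt_scale * (sum OAV)^dt_exponent`, perturbed by multiplicative
#' lognormal noise — the generating link that [oav_dt_correlation()] is
#' expected to recover on the log-log scale.
#'
#' @param oav_sums Data.frame `day`, `sum_oav` with positive sums.
#' @param scenario A [study_scenario()].
#' @return Data.frame `day`, `dt_ratio`.
#' @export
generate_dt <- function(oav_sums, scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  if (any(oav_sums$sum_oav <= 0)) stop("sum_oav must be > 0")
  set.seed(scenario$seed + 2L)
  data.frame(day = oav_sums$day,
             dt_ratio = scenario$dt_scale *
               oav_sums$sum_oav^scenario$dt_exponent *
               stats::rlnorm(nrow(oav_sums), 0, scenario$noise_sigma))
}
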