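---
title: "Methods: semi-quantification and odor-activity profiling of fruit volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantification and odor-activity profiling of fruit volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromaq)
```

## The problem

Headspace GC-MS of stored fruit detects far more volatile organic compounds
(VOCs) than anyone can buy authentic standards for. To put *all* detected
compounds on a quantitative footing, `aromaq` implements the
effective-carbon-number (ECN) semi-quantification strategy: calibrate a
modest standard mixture externally, regress the standards' response factors
on their ECN values, and use the fitted line to predict a response factor —
and hence a concentration — for every compound lacking a standard. The
concentrations then feed an odor-centric profile: relative mass composition
(RC), odor activity values (OAV), relative proportions (RP) and their trends
over storage time.

## Effective carbon number

Each atom and oxygen-bearing moiety of a C/H/O molecule contributes a fixed
"carbon number equivalent" to the mass-spectrometric response:

$$\mathrm{ECN} = n_C \cdot 1 + n_H \cdot (-0.035) + n_O \cdot 0
  + n_{>C=O} \cdot (-0.95) + n_{-O-} \cdot 0.55 + n_{-CH_3} \cdot 0.15$$

An ester linkage $-C(=O)-O-$ counts as one carbonyl *plus* one ether: those
are the only two oxygen moieties in the scheme and the scheme is routinely
applied to esters, so the linkage must decompose into them. Moiety counts
are registry *inputs*, taken from the curated table, not derived from
structures — the workflow has no structure representation, only formulas.
Compounds with elements beyond C/H/O (S- or Cl-bearing volatiles) are
registry-valid but ECN-ineligible: they are quantified only when a direct
standard exists, and otherwise reported missing rather than extrapolated.

```{r ecn}
compute_ecn(moiety_counts(4, 8, 2, 1, 1, 2))   # ethyl acetate: 3.62
```

## Calibration and the RF-ECN model

The response factor (RF, peak area per ng) of each standard is the
**zero-intercept** least-squares slope of area on loading — external
calibration through the origin. The source experiment reports single RF
values per compound and day without defining the estimator; through-origin
least squares is the standard convention for origin-anchored external
calibration, and a mean-of-ratios estimator is available as an option.
Batch-to-batch stability is summarised by CV% (sample SD over mean, n-1
denominator — the denominator is a convention choice; the sample SD is the
unbiased default) and repeatability by RSE% (CV over $\sqrt n$).

`fit_rf_vs_ecn()` then fits one ordinary least-squares line
$RF = a \cdot ECN + b$ over **all** standards. Whether the source analysis
fitted globally or per functional class is not stated; the global fit is the
default because a single predictive equation is described, and a per-group
option (`regression_scope = "per_group"` in `quantify_study()`) is provided
for users who prefer class-specific response models. Predicted RFs that come
out non-positive raise an out-of-range error instead of producing negative
concentrations.

Concentration follows from the sampling geometry: the default 50 mL/min for
1 min sweeps $5\times10^{-5}\,\mathrm{m^3}$ of headspace, so
$c\,[\mu g\,m^{-3}] = (\mathrm{area}/RF)\,[\mathrm{ng}] / 5\times10^{-5}\,
[\mathrm{m^3}] / 1000$.

### Unit conversion

ppbv and $\mu g\,m^{-3}$ interconvert through the ideal-gas molar volume:
$\mu g\,m^{-3} = \mathrm{ppbv} \times MW / V_m$. The default
$V_m = 24.5\,\mathrm{L\,mol^{-1}}$ was back-derived from the dual-unit pairs
of the packaged study table (e.g. acetaldehyde 1,618 ppb against 2,909
$\mu g\,m^{-3}$ implies 24.50 exactly); the experiment ran at 25 °C but
never printed the constant. It is configurable everywhere it is used.

## The packaged storage study and its precision

`strawberry_registry()` / `strawberry_concentrations()` ship a transcription
of the published summary tables of a nine-day strawberry storage experiment:
53 major volatiles (relative composition above 0.05 % on at least one of
days 0, 1, 3, 6, 9) in six functional groups. Two transcription choices
matter:

* **Thresholds are back-solved.** The literature odor-threshold survey
  behind the published OAVs is not public. Each compound's working threshold
  is therefore recovered as `concentration / OAV` from the printed day whose
  OAV cell carries the most significant digits. One compound (mesifurane)
  has no readable per-compound OAV cells at all, but its group's summed OAV
  exceeds the sum of the other members by a consistent amount on three
  independent days; the implied threshold (3.27 ppbv, spread 3.22-3.31) is
  used for it. These are derived working values, labelled `backsolved` in
  the registry, not surveyed records.
* **Tolerances follow printed precision.** Many cells carry only 1-2
  significant figures, so fixture checks allow 0.5 % (sums, concentrations)
  or 1.5 % (OAV cells) *plus* half a unit in the last printed digit of each
  number entering the comparison. Without that propagation a printed "0.03
  ppb" cell would fail any fixed relative band through no fault of the
  arithmetic.

Below-detection (BDL) entries hold the method detection limit as a
placeholder, the source's convention (`apply_mdl()` reproduces it).
"Detected" always means *not* BDL, and by default the placeholders are
excluded from group sums as well: the published summed rows match the
detected-only sums at printed precision on every day, while including the
placeholders overshoots the day-9 ester sum by ~1 %. The `include_bdl` flag
restores them. For OAV the default likewise excludes BDL entries (a
non-detection has no meaningful odor activity; the published OAV table
leaves those cells blank), with a strict flag to include the placeholders.

Relative composition uses externally supplied day totals because the study's
totals cover all 147 detected compounds, not only the 53 printed majors; the
RC of any printed subset therefore sums to less than 100 %.

## Odor activity

$\mathrm{OAV} = c_{\mathrm{ppbv}} / \mathrm{threshold}_{\mathrm{ppbv}}$.
When several literature thresholds exist, the **maximum** is selected by
default — the conservative choice, and the statistic with the strongest
threshold-molecular-weight correlation; `min` and `geomean` policies are
available and obey $\mathrm{OAV}_{min} \ge \mathrm{OAV}_{geomean} \ge
\mathrm{OAV}_{max}$. Compounds without thresholds keep an `NA` OAV and never
enter a denominator. RP is the percent share of a day's summed OAV;
`period_aggregate()` sums OAVs over a day subset (e.g. the fresh period) and
reports a compound subset's share of the period total.

## Trend regressions

All trend fits are ordinary least squares via `ols_fit()`, with the p-value
from the two-sided t-test on the slope (reported for $n \ge 3$; no
multiple-testing correction, matching the source analyses). Log base 10 is
used throughout: in log-log fits the base only shifts the intercept, but in
the semi-log intensity-versus-day fit it scales the slope, and base 10
reproduces the magnitude class of the published decay slopes.
`threshold_mw_regression()` fits $\log_{10}(\mathrm{threshold})$ on MW,
pooled and/or per group (groups with fewer than three threshold-bearing
compounds are skipped with a warning); outlier trimming is only ever an
explicit, user-supplied exclusion list because no trimming rule is published.
`oav_dt_correlation()` fits $\log_{10}(D/T)$ on
$\log_{10}(\Sigma \mathrm{OAV})$, so a power law $D/T = c \cdot
(\Sigma\mathrm{OAV})^k$ is recovered with slope $k$; $R^2$ and the p-value
are direction-invariant.

## The synthetic generator

`study_scenario()` fixes the conditions the generators emulate; the defaults
mirror the packaged study and are not tuning knobs:

* group census 23/11/5/5/2/7 (ester/alcohol/aldehyde/ketone/fatty
  acid/miscellaneous), day grid {0, 1, 3, 6, 9};
* group dynamics anchored to the study's summed-concentration trajectories:
  esters rise ~13x to a day-3 peak then collapse more than three orders of
  magnitude; alcohols climb ~3 orders of magnitude to a day-6 peak; the
  remaining classes fade (log-linear interpolation between anchors);
* multiplicative lognormal noise on peak areas with $\sigma = 0.02$,
  matching the instrument's sub-4 % response-factor variability;
* a generating RF line $RF = 40 \cdot ECN + 5$ (the scale of the worked
  examples), thresholds scattered lognormally ($\sigma = 0.5$ log units,
  the typical spread of literature replicates) around a class mean falling
  with MW (slope -0.02 per g/mol), and a $D/T \propto
  \sqrt{\Sigma\mathrm{OAV}}$ sensory link.

The generator reproduces the *statistical structure* the analysis assumes —
positive multiplicative noise, linear RF-ECN response, lognormal threshold
scatter, the fresh-to-decay group dynamics — but not chromatography itself:
no retention times, co-elutions, baseline drift or library-search
misidentifications. Passing recovery tests therefore demonstrates that the
pipeline inverts its own measurement model faithfully, not that real peak
tables are error-free.

With `noise_sigma = 0` the end-to-end pipeline (calibration fits, RF-ECN
regression, quantification) reproduces the generating concentrations to
machine precision, and with $\sigma = 0.02$ about 95 % of entries recover
within 5 %. One recovery limit is worth stating plainly: the RF-ECN *slope*
recovers within ~1 %, but the *intercept* (true value 5 against RFs of
85-365) has an OLS sampling SE near 1 under 2 % area noise with 19
standards, so its relative error is typically 10-30 %. Quantification is
insensitive to this — predicted RFs inside the calibrated ECN range recover
within ~1 % — but intercept estimates from a 19-standard calibration should
not be over-interpreted.

## Numerical choices and degenerate inputs

* Calibration with identical loadings, RF-ECN fits with a single distinct
  ECN, and trend fits with constant x all raise degenerate-design errors.
* The uncentered $R^2$ is used for through-origin calibration (bounded in
  [0, 1], unlike the centered version for a forced origin).
* Zero areas quantify to zero; non-positive thresholds, molar volumes, flow
  rates and RFs are rejected at the boundary with named errors.
* Geometric means of thresholds are computed in log space.
* Generator seeds are plain integers; every generator call is a
  deterministic function of its scenario (same seed, same bytes).

Problem sizes in the shipped tests and acceptance script: the 53-compound
packaged study, synthetic studies of 53 compounds x 5 days, 19-standard
calibrations at 5 loadings x 5 batches, and seed batteries of 10 — each run
completes in seconds.

## Known limitations

* The ECN scheme covers C/H/O compounds only; S-, N- and Cl-bearing
  volatiles need authentic standards.
* Back-solved thresholds inherit the rounding of the published tables
  (1-2 significant figures for minor compounds) and cannot be traced to
  their original literature sources.
* The OAV framework treats odorants independently: no mixture suppression,
  masking or synergy, and no psychophysical intensity scaling beyond the
  plain concentration/threshold ratio.
* The 94 minor compounds of the full 147-compound study are not
  reconstructable from the published majors; study-wide totals are carried
  as data instead.
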