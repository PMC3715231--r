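Package: aromaq
Title: Quantification and Odor-Activity Profiling of Fruit Volatiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative analysis of volatile organic compounds
    (VOCs) released from stored fruit and measured by thermal-desorption GC-MS.
    Implements effective-carbon-number (ECN) prediction of mass-spectrometric
    response factors, so that compounds lacking authentic calibration standards
    can be quantified from a linear response-factor-versus-ECN regression fitted
    to an externally calibrated standard mixture; external calibration fits with
    coefficient-of-variation and relative-standard-error quality control;
    conversion between ppbv and microgram-per-cubic-metre concentration units;
    concentration tables across storage days with below-detection-limit
    handling, functional-group aggregation, and relative-composition profiling;
    odor activity values (OAV = concentration / odor threshold) under
    configurable literature-threshold selection policies, with relative
    proportions and storage-period aggregates; log-linear trend regressions
    (odor threshold versus molecular weight, odor intensity versus storage day,
    OAV versus dilution-to-threshold sensory ratio); and seeded synthetic-data
    generators emulating the fresh-to-decay dynamics of fruit aroma profiles.
    Ships a worked strawberry storage data set transcribed from the published
    summary tables of a nine-day storage experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
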