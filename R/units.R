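#' Headspace sampling geometry
#'
#' Describes the sorbent-tube sampling of the fruit headspace: a carrier-gas
#' flow through the sample vessel for a fixed duration. The sampled volume
#' (flow rate x duration) converts collected analyte mass to a headspace
#' concentration. The default is 50 mL/min for 1 min, i.e. 5e-5 m^3.
#'
#' @param flow_rate_ml_min Carrier flow in mL/min.
#' @param duration_min Sampling duration in minutes.
#' @return A list with `flow_rate_ml_min`, `duration_min` and the derived
#'   `sampled_volume_m3`, of class `"sampling_geometry"`.
#' @export
sampling_geometry <- function(flow_rate_ml_min = 50, duration_min = 1) {
  if (!is.finite(flow_rate_ml_min) || flow_rate_ml_min <= 0)
    stop("flow_rate_ml_min must be > 0")
  if (!is.finite(duration_min) || duration_min <= 0)
    stop("duration_min must be > 0")
  structure(list(flow_rate_ml_min = flow_rate_ml_min,
                 duration_min = duration_min,
                 sampled_volume_m3 = flow_rate_ml_min * duration_min * 1e-6),
            class = "sampling_geometry")
}

#' @export
print.sampling_geometry <- function(x, ...) {
  cat(sprintf("Sampling geometry: %.3g mL/min for %.3g min -> %.3g m^3\n",
              x$flow_rate_ml_min, x$duration_min, x$sampled_volume_m3))
  invisible(x)
}

#' Convert between ppbv and microgram per cubic metre
#'
#' Ideal-gas conversion at the study temperature:
#' `ug/m^3 = ppbv * MW / Vm`, with `Vm` the molar volume in L/mol
#' (default 24.5, appropriate near 25 degrees C).
#'
#' @param ppb Concentration(s) in ppbv.
#' @param ugm3 Concentration(s) in ug/m^3.
#' @param mw Molecular weight(s) in g/mol.
#' @param molar_volume Molar volume in L/mol (> 0).
#' @return Converted concentration(s); the two functions are exact inverses.
#' @examples
#' ppb_to_ugm3(1618, 44.05)  # acetaldehyde, ~2909 ug/m^3
#' @export
ppb_to_ugm3 <- function(ppb, mw, molar_volume = 24.5) {
  check_conversion_args(mw, molar_volume)
  ppb * mw / molar_volume
}

#' @rdname ppb_to_ugm3
#' @export
ugm3_to_ppb <- function(ugm3, mw, molar_volume = 24.5) {
  check_conversion_args(mw, molar_volume)
  ugm3 * molar_volume / mw
}

check_conversion_args <- function(mw, molar_volume) {
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("mw must be positive and finite")
  if (!is.finite(molar_volume) || molar_volume <= 0)
    stop("molar_volume must be positive and finite")
  invisible(TRUE)
}
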