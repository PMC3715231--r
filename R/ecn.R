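#' Carbon-number-equivalent coefficients for the ECN scheme
#'
#' The effective carbon number (ECN) of a C/H/O volatile is a unitless score
#' that predicts its mass-spectrometric response: each atom or functional
#' moiety contributes a fixed "carbon number equivalent" (CNE). The default
#' contributions are C = 1, H = -0.035, O = 0, carbonyl (>C=O) = -0.95,
#' ether-type linkage (-O-) = 0.55 and methyl (-CH3) = 0.15.
#'
#' @param c_C,c_H,c_O,c_carbonyl,c_ether,c_methyl Per-atom / per-moiety CNE
#'   contributions.
#' @return A named numeric vector of class `"ecn_coefficients"`.
#' @examples
#' ecn_coefficients()
#' @export
ecn_coefficients <- function(c_C = 1, c_H = -0.035, c_O = 0,
                             c_carbonyl = -0.95, c_ether = 0.55,
                             c_methyl = 0.15) {
  k <- c(c_C = c_C, c_H = c_H, c_O = c_O, c_carbonyl = c_carbonyl,
         c_ether = c_ether, c_methyl = c_methyl)
  if (any(!is.finite(k))) stop("ECN coefficients must be finite")
  structure(k, class = "ecn_coefficients")
}

#' Compute effective carbon numbers
#'
#' ECN = n_C * c_C + n_H * c_H + n_O * c_O + n_carbonyl * c_carbonyl +
#' n_ether * c_ether + n_methyl * c_methyl, evaluated row-wise.
#'
#' @param m Moiety counts: a data.frame (or one-row list) with columns
#'   `n_C`, `n_H`, `n_O`, `n_carbonyl`, `n_ether`, `n_methyl` — e.g. a
#'   validated registry or the result of [moiety_counts()].
#' @param k Coefficients from [ecn_coefficients()].
#' @return Numeric vector of ECN values, one per row of `m` (named by
#'   `m$name` when present).
#' @examples
#' # n-pentane: 5 - 12*0.035 + 2*0.15 = 4.88
#' compute_ecn(moiety_counts(5, 12, 0, 0, 0, 2))
#' # ethyl acetate: 4 - 8*0.035 - 0.95 + 0.55 + 2*0.15 = 3.62
#' compute_ecn(moiety_counts(4, 8, 2, 1, 1, 2))
#' @export
compute_ecn <- function(m, k = ecn_coefficients()) {
  if (!inherits(k, "ecn_coefficients")) k <- do.call(ecn_coefficients, as.list(k))
  m <- as.data.frame(m)
  validate_moieties(m)
  ecn <- m$n_C * k[["c_C"]] + m$n_H * k[["c_H"]] + m$n_O * k[["c_O"]] +
    m$n_carbonyl * k[["c_carbonyl"]] + m$n_ether * k[["c_ether"]] +
    m$n_methyl * k[["c_methyl"]]
  if (!is.null(m$name)) names(ecn) <- m$name
  ecn
}

#' Add ECN values to a registry
#'
#' Computes ECN for every ECN-eligible compound (pure C/H/O molecules with
#' moiety counts); others get `NA` and must be quantified against a direct
#' authentic standard.
#'
#' @param registry A validated registry.
#' @param k Coefficients from [ecn_coefficients()].
#' @return The registry with an `ecn` column added.
#' @export
add_ecn <- function(registry, k = ecn_coefficients()) {
  ecn <- rep(NA_real_, nrow(registry))
  el <- which(registry$ecn_eligible)
  if (length(el)) ecn[el] <- unname(compute_ecn(registry[el, , drop = FALSE], k))
  registry$ecn <- ecn
  registry
}
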