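#' Parse a Hill-style elemental formula
#'
#' Tokenises a formula string such as `"C4H8O2"` into element counts. Carbon,
#' hydrogen and oxygen are returned explicitly because they feed the
#' effective-carbon-number (ECN) scheme; any other element (S, Cl, N, ...)
#' is counted too but flagged, since the ECN contribution table covers only
#' C/H/O atoms and their oxygen-bearing moieties.
#'
#' @param formula Character scalar, e.g. `"C4H8O2"`, `"CH4"`, `"C2H6OS"`.
#'   Element symbols with optional integer counts; an omitted count means 1.
#' @return A list with components `C`, `H`, `O` (integer counts), `other`
#'   (named integer vector of non-CHO elements, possibly empty) and
#'   `has_other` (logical flag).
#' @examples
#' parse_formula("C4H8O2")   # ethyl acetate: C 4, H 8, O 2
#' parse_formula("C2H6OS")$has_other  # sulfur flagged
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("'formula' must be a single character string")
  s <- trimws(formula)
  if (!nzchar(s)) stop("'formula' is empty")
  counts <- integer(0)
  pos <- 1L
  while (pos <= nchar(s)) {
    rest <- substr(s, pos, nchar(s))
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop(sprintf("malformed formula '%s': unexpected token at position %d ('%s')",
                   s, pos, substr(s, pos, pos)))
    el <- m[2]
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    pos <- pos + nchar(m[1])
  }
  cho <- c(C = 0L, H = 0L, O = 0L)
  for (el in intersect(names(counts), names(cho))) cho[el] <- counts[[el]]
  other <- counts[setdiff(names(counts), names(cho))]
  list(C = unname(cho["C"]), H = unname(cho["H"]), O = unname(cho["O"]),
       other = other, has_other = length(other) > 0L)
}

#' Compose a C/H/O formula string from atom counts
#'
#' Inverse of [parse_formula()] for pure C/H/O molecules (Hill order).
#'
#' @param C,H,O Non-negative integer atom counts.
#' @return Character formula string.
#' @export
compose_formula <- function(C, H, O = 0L) {
  stopifnot(C >= 0, H >= 0, O >= 0)
  part <- function(sym, n) if (n == 0L) "" else if (n == 1L) sym else paste0(sym, n)
  out <- paste0(part("C", C), part("H", H), part("O", O))
  if (!nzchar(out)) stop("empty molecule")
  out
}

# Monoisotopic-free average atomic masses used for registry MW checks.
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999, S = 32.06, Cl = 35.453,
                  N = 14.007, F = 18.998, Br = 79.904)

#' Molecular weight from an elemental formula
#'
#' @param formula Character scalar formula.
#' @return Molecular weight in g/mol.
#' @export
formula_mw <- function(formula) {
  p <- parse_formula(formula)
  ct <- c(C = p$C, H = p$H, O = p$O, p$other)
  unknown <- setdiff(names(ct), names(.atomic_mass))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  sum(.atomic_mass[names(ct)] * ct)
}

#' Moiety counts for the ECN scheme
#'
#' Bundles the atom and functional-moiety counts that enter the
#' effective-carbon-number computation: C, H and O atoms, carbonyl groups
#' (>C=O), ether-type linkages (-O-) and methyl groups (-CH3). An ester
#' linkage -C(=O)-O- counts as one carbonyl plus one ether.
#'
#' @param n_C,n_H,n_O,n_carbonyl,n_ether,n_methyl Non-negative integer counts.
#' @return A one-row data.frame of validated counts.
#' @export
moiety_counts <- function(n_C, n_H, n_O, n_carbonyl = 0L, n_ether = 0L,
                          n_methyl = 0L) {
  m <- data.frame(n_C = n_C, n_H = n_H, n_O = n_O, n_carbonyl = n_carbonyl,
                  n_ether = n_ether, n_methyl = n_methyl)
  validate_moieties(m)
  m
}

validate_moieties <- function(m, where = "moiety counts") {
  cols <- c("n_C", "n_H", "n_O", "n_carbonyl", "n_ether", "n_methyl")
  missing <- setdiff(cols, names(m))
  if (length(missing))
    stop(where, ": missing column(s) ", paste(missing, collapse = ", "))
  for (cl in cols) {
    v <- m[[cl]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("%s: %s must be non-negative integers (row %d)",
                   where, cl, bad[1]))
  }
  bad <- which(m$n_carbonyl + m$n_ether > m$n_O)
  if (length(bad))
    stop(sprintf("%s: n_carbonyl + n_ether exceeds n_O (row %d)", where, bad[1]))
  bad <- which(3 * m$n_methyl > m$n_H)
  if (length(bad))
    stop(sprintf("%s: 3 * n_methyl exceeds n_H (row %d)", where, bad[1]))
  invisible(TRUE)
}

.vocs_groups <- c("ester", "alcohol", "aldehyde", "ketone", "fatty_acid", "etc")

#' Validate a compound registry
#'
#' Checks a raw registry table and returns a validated registry data.frame.
#' The registry is the unit of chemical metadata consumed by every downstream
#' stage: identity, formula, molecular weight, functional-group class, moiety
#' counts for the ECN scheme, literature odor thresholds and descriptors.
#'
#' Validation enforces: positive molecular weight; a functional class from the
#' six-group scheme (`ester`, `alcohol`, `aldehyde`, `ketone`, `fatty_acid`,
#' `etc`); unique names; moiety-count invariants; and, where both a formula
#' and moiety counts are given, agreement of the formula's C/H/O counts with
#' `n_C`/`n_H`/`n_O`. Compounds without any threshold are retained but are
#' ineligible for odor-activity values (`oav_eligible = FALSE`); compounds
#' containing elements beyond C/H/O are flagged ECN-ineligible
#' (`ecn_eligible = FALSE`) and are quantified only via a direct standard.
#'
#' @param rows A data.frame with at least `name`, `group`, `mw`. Optional:
#'   `formula`, moiety-count columns, `thresholds` (either a list-column of
#'   numeric vectors or a character column `"v1@src1;v2@src2"`),
#'   `descriptors`, `is_standard`.
#' @return A data.frame with class `c("aroma_registry", "data.frame")`;
#'   `thresholds` is a list-column of numeric ppbv vectors,
#'   `threshold_sources` a parallel list-column of citation keys.
#' @seealso [read_registry()] to load the CSV dialect directly.
#' @export
validate_registry <- function(rows) {
  if (is.null(rows) || nrow(as.data.frame(rows)) == 0L) {
    out <- data.frame(name = character(0), formula = character(0),
                      mw = numeric(0), group = character(0))
    class(out) <- c("aroma_registry", "data.frame")
    return(out)
  }
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- setdiff(c("name", "group", "mw"), names(df))
  if (length(need))
    stop("registry is missing required column(s): ", paste(need, collapse = ", "))

  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop("duplicate compound name(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(is.na(df$mw) | df$mw <= 0)
  if (length(bad))
    stop(sprintf("invalid mw for compound '%s' (row %d): mw must be > 0",
                 df$name[bad[1]], bad[1]))
  bad <- which(!(df$group %in% .vocs_groups))
  if (length(bad))
    stop(sprintf("unknown group '%s' for compound '%s' (row %d); expected one of %s",
                 df$group[bad[1]], df$name[bad[1]], bad[1],
                 paste(.vocs_groups, collapse = ", ")))

  has_moieties <- all(c("n_C", "n_H", "n_O") %in% names(df))
  if (has_moieties) {
    for (cl in c("n_carbonyl", "n_ether", "n_methyl"))
      if (!cl %in% names(df)) df[[cl]] <- 0L
    validate_moieties(df, where = "registry")
  }

  ecn_eligible <- rep(has_moieties, nrow(df))
  if ("formula" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      f <- df$formula[i]
      if (is.na(f) || !nzchar(f)) next
      p <- parse_formula(f)
      if (p$has_other) ecn_eligible[i] <- FALSE
      if (has_moieties &&
          (p$C != df$n_C[i] || p$H != df$n_H[i] || p$O != df$n_O[i]))
        stop(sprintf(
          "compound '%s' (row %d): formula %s (C%d H%d O%d) disagrees with moiety counts (C%d H%d O%d)",
          df$name[i], i, f, p$C, p$H, p$O, df$n_C[i], df$n_H[i], df$n_O[i]))
    }
  }
  df$ecn_eligible <- ecn_eligible

  # thresholds: accept list-column of numerics or "value@source;value@source"
  if (!"thresholds" %in% names(df)) {
    df$thresholds <- replicate(nrow(df), numeric(0), simplify = FALSE)
    df$threshold_sources <- replicate(nrow(df), character(0), simplify = FALSE)
  } else if (!is.list(df$thresholds)) {
    parsed <- lapply(as.character(df$thresholds), parse_threshold_field)
    df$thresholds <- lapply(parsed, `[[`, "values")
    df$threshold_sources <- lapply(parsed, `[[`, "sources")
  } else if (!"threshold_sources" %in% names(df)) {
    df$threshold_sources <- lapply(df$thresholds,
                                   function(v) rep("unsourced", length(v)))
  }
  for (i in seq_len(nrow(df))) {
    v <- df$thresholds[[i]]
    if (length(v) && any(is.na(v) | v <= 0))
      stop(sprintf("compound '%s' (row %d): odor thresholds must be > 0 ppbv",
                   df$name[i], i))
  }
  df$oav_eligible <- vapply(df$thresholds, function(v) length(v) > 0L, TRUE)

  if (!"is_standard" %in% names(df)) df$is_standard <- FALSE
  if (!"descriptors" %in% names(df)) df$descriptors <- ""
  class(df) <- c("aroma_registry", "data.frame")
  df
}

parse_threshold_field <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)))
    return(list(values = numeric(0), sources = character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  vals <- numeric(0); srcs <- character(0)
  for (p in parts) {
    p <- trimws(p)
    if (!nzchar(p)) next
    kv <- strsplit(p, "@", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(kv[1]))
    if (is.na(v)) stop("cannot parse threshold entry '", p, "'")
    vals <- c(vals, v)
    srcs <- c(srcs, if (length(kv) > 1L) kv[2] else "unsourced")
  }
  list(values = vals, sources = srcs)
}

#' @export
print.aroma_registry <- function(x, ...) {
  cat(sprintf("Compound registry: %d compounds, %d groups\n",
              nrow(x), length(unique(x$group))))
  if (nrow(x)) {
    tab <- table(factor(x$group, levels = .vocs_groups))
    cat("  by group:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  with odor threshold(s): %d of %d; ECN-eligible: %d; authentic standards: %d\n",
                sum(x$oav_eligible), nrow(x), sum(x$ecn_eligible), sum(x$is_standard)))
  }
  invisible(x)
}

#' Selected odor threshold per registry compound
#'
#' Applies a threshold-selection policy compound-wise (see
#' [select_threshold()]) and returns one ppbv value per compound (NA where a
#' compound carries no literature threshold).
#'
#' @param registry A validated registry.
#' @param policy `"max"` (default), `"min"` or `"geomean"`.
#' @return Named numeric vector of thresholds in ppbv.
#' @export
registry_thresholds <- function(registry, policy = c("max", "min", "geomean")) {
  policy <- match.arg(policy)
  out <- vapply(registry$thresholds, function(v) {
    if (!length(v)) NA_real_ else select_threshold(v, policy)
  }, numeric(1))
  names(out) <- registry$name
  out
}
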