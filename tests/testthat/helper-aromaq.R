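# Shared helpers for the test suite.

# Significant figures of a printed number (as stored from the transcribed
# tables) and its unit-in-the-last-place: used to propagate the rounding of
# the source tables into comparison tolerances.
printed_sigfigs <- function(x) {
  s <- formatC(x, format = "g", digits = 15)
  mant <- sub("[eE].*$", "", s)
  d <- gsub("[^0-9]", "", mant)
  d <- sub("^0+", "", d)
  nchar(d)
}

printed_ulp <- function(x) {
  10^(floor(log10(abs(x))) - (printed_sigfigs(x) - 1))
}

# Independent brute-force ECN oracle: expands the molecule into an explicit
# list of per-atom / per-moiety contributions and sums them one by one.
ecn_bruteforce <- function(n_C, n_H, n_O, n_carbonyl, n_ether, n_methyl,
                           k = c(1, -0.035, 0, -0.95, 0.55, 0.15)) {
  contribs <- c(rep(k[1], n_C), rep(k[2], n_H), rep(k[3], n_O),
                rep(k[4], n_carbonyl), rep(k[5], n_ether),
                rep(k[6], n_methyl))
  total <- 0
  for (cc in contribs) total <- total + cc
  total
}

# Closed-form simple-OLS oracle via the explicit normal equations.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Random valid moiety-count sets for property tests.
random_moieties <- function(n) {
  nC <- sample(1:12, n, replace = TRUE)
  nO <- sample(0:3, n, replace = TRUE)
  ncb <- mapply(function(o, cc) sample(0:min(o, cc), 1), nO, nC)
  net <- mapply(function(o, cb) sample(0:(o - cb), 1), nO, ncb)
  nH <- 2 * nC + 2 - 2 * ncb          # saturated skeleton, ring-free
  nme <- mapply(function(h) sample(0:(h %/% 3), 1), nH)
  data.frame(n_C = nC, n_H = nH, n_O = nO, n_carbonyl = ncb,
             n_ether = net, n_methyl = nme)
}

fixture_registry <- function() strawberry_registry()
fixture_conc <- function() strawberry_concentrations()
fixture_totals <- function() {
  t1 <- strawberry_group_summary()
  with(t1[t1$group == "all", ], stats::setNames(sum_ugm3, day))
}
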