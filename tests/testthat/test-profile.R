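test_that("apply_mdl stores the detection limit for sub-MDL entries", {
  conc <- data.frame(compound = c("a", "a", "b"), day = c(0, 1, 0),
                     conc_ppb = c(0, 5, 0.01))
  out <- apply_mdl(conc, c(a = 0.02, b = 0.02))
  expect_equal(out$conc_ppb, c(0.02, 5, 0.02))
  expect_equal(out$bdl, c(TRUE, FALSE, TRUE))
  expect_equal(out$mdl_value, c(0.02, 0.02, 0.02))
  expect_error(apply_mdl(conc, c(a = 0.02)), "no MDL")
  expect_error(apply_mdl(conc, c(a = 0.02, b = -1)), "> 0")
})

test_that("group sums conserve the all-compound total", {
  conc <- fixture_conc()
  reg <- fixture_registry()
  for (flag in c(TRUE, FALSE)) {
    gs <- group_sums(conc, reg, include_bdl = flag)
    per_day_groups <- tapply(gs$sum_ugm3, gs$day, sum)
    sel <- if (flag) rep(TRUE, nrow(conc)) else !conc$bdl
    per_day_all <- tapply(conc$conc_ugm3[sel], conc$day[sel], sum)
    expect_equal(per_day_groups, per_day_all, tolerance = 1e-12)
  }
})

test_that("group sums reproduce the published summed rows", {
  gs <- group_sums(fixture_conc(), fixture_registry())
  pick <- function(g, d) gs$sum_ugm3[gs$group == g & gs$day == d]
  expect_equal(pick("ester", 0), 52346, tolerance = 0.005)
  expect_equal(pick("ester", 9), 44.7, tolerance = 0.005)
  expect_equal(pick("alcohol", 9), 4651, tolerance = 0.005)
  expect_equal(pick("aldehyde", 3), 19035, tolerance = 0.005)
})

test_that("empty groups sum to zero with zero detections", {
  conc <- data.frame(compound = "x", day = c(0, 1), conc_ugm3 = c(1, 2),
                     group = "ester", bdl = c(FALSE, TRUE))
  gs <- group_sums(conc)
  expect_equal(gs$n_detected, c(1, 0))
  expect_equal(gs$sum_ugm3, c(1, 0))
})

test_that("relative composition matches the printed anchor percentages", {
  rc <- relative_composition(fixture_conc(), fixture_totals())
  pick <- function(cp, d) rc$rc[rc$compound == cp & rc$day == d]
  expect_equal(pick("Ethyl acetate", 0), 25.1, tolerance = 0.005)
  expect_equal(pick("Isobutyl alcohol", 6), 75.3, tolerance = 0.005)
  expect_equal(pick("Methyl acetate", 0), 17.4, tolerance = 0.005)
  # subset RC never exceeds 100 per day
  expect_true(all(tapply(rc$rc, rc$day, sum) <= 100 + 1e-9))
  expect_error(relative_composition(fixture_conc(), c(`0` = 0)), "day|> 0")
})

test_that("single-compound table at its own total gives RC = 100%", {
  conc <- data.frame(compound = "x", day = 0, conc_ugm3 = 42)
  expect_equal(relative_composition(conc, c(`0` = 42))$rc, 100)
})

test_that("major-compound selection applies the RC cutoff per day", {
  rc <- data.frame(compound = c("lo", "lo", "edge", "hi"),
                   day = c(0, 1, 1, 0),
                   rc = c(0.04, 0.03, 0.06, 2))
  sel <- select_major(rc)
  expect_setequal(sel$compound, c("edge", "hi"))
  expect_equal(sel$qualifying_days[sel$compound == "edge"], "1")
})

test_that("select_major is monotone in the cutoff", {
  set.seed(23)
  rc <- data.frame(compound = rep(sprintf("c%03d", 1:100), each = 3),
                   day = rep(c(0, 1, 3), 100),
                   rc = 10^runif(300, -4, 1))
  cuts <- c(0.01, 0.05, 0.2, 1)
  ns <- vapply(cuts, function(ct) nrow(select_major(rc, ct)), 0)
  expect_true(all(diff(ns) <= 0))
})

test_that("a table built with exactly 53 over-cutoff compounds returns 53", {
  set.seed(29)
  n <- 147
  peak <- numeric(n)
  peak[1:53] <- 10^runif(53, log10(0.051), 1)   # constructed to qualify
  peak[54:n] <- 10^runif(n - 53, -4, log10(0.049))
  rc <- data.frame(compound = rep(sprintf("c%03d", 1:n), each = 5),
                   day = rep(c(0, 1, 3, 6, 9), n),
                   rc = as.vector(vapply(peak, function(p)
                     p * c(1, runif(4, 0, 1)), numeric(5))))
  expect_equal(nrow(select_major(rc, 0.05)), 53)
})

test_that("consistency counts equal brute-force set intersections", {
  set.seed(31)
  compounds <- sprintf("c%02d", 1:30)
  groups <- sample(c("ester", "alcohol"), 30, replace = TRUE)
  days <- c(0, 1, 3, 6, 9)
  conc <- expand.grid(compound = compounds, day = days,
                      stringsAsFactors = FALSE)
  conc$group <- groups[match(conc$compound, compounds)]
  conc$conc_ugm3 <- 1
  conc$bdl <- runif(nrow(conc)) < 0.4
  cc <- consistency_counts(conc)
  for (g in unique(groups)) for (i in 2:5) {
    cur <- conc$compound[conc$group == g & conc$day == days[i] & !conc$bdl]
    prev <- conc$compound[conc$group == g & conc$day == days[i - 1] & !conc$bdl]
    expect_equal(cc$n_consistent[cc$group == g & cc$day == days[i]],
                 length(intersect(cur, prev)))
  }
  # identical consecutive detection sets: consistent count = detected count
  conc$bdl <- rep(conc$bdl[conc$day == 0], times = 5)
  cc2 <- consistency_counts(conc)
  gs2 <- group_sums(conc)
  later <- cc2$day != 0
  expect_equal(cc2$n_consistent[later], gs2$n_detected[later])
})
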