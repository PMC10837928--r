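# A hand-built incidence surface over 2 diseases and explicit ages.
make_surface <- function(diseases, rows) {
  structure(rows, diseases = diseases,
            class = c("incidence_surface", class(tibble::tibble())))
}

two_disease_surface <- function() {
  make_surface(c("A", "B"), tibble::tibble(
    sex = "male",
    age = rep(c(70L, 71L), 4),
    target = rep(c("A", "A", "B", "B"), each = 2),
    state = rep(c("00", "01", "00", "10"), each = 2),
    incidence = c(0.01, 0.02, 0.015, 0.03, 0.02, 0.02, 0.025, 0.03),
    flagged = FALSE))
}

test_that("difference series subtracts the healthy state age by age", {
  surf <- two_disease_surface()
  ds <- difference_series(surf, "A", "01", "male")
  expect_equal(ds$age, c(70L, 71L))
  expect_equal(ds$diff, c(0.015 - 0.01, 0.03 - 0.02))
  expect_error(difference_series(surf, "A", "11", "male"), "own bit")
  expect_error(difference_series(surf, "A", "00", "male"), "at least one")
})

test_that("flagged ages are excluded from the difference series", {
  surf <- two_disease_surface()
  surf$flagged[surf$target == "A" & surf$state == "01" & surf$age == 71] <- TRUE
  ds <- difference_series(surf, "A", "01", "male")
  expect_equal(ds$age, 70L)
  expect_equal(ds$diff, 0.005)
})

test_that("the t-interval summary matches the hand-computed case", {
  ds <- structure(tibble::tibble(age = 70:71, diff = c(0.004, 0.006)),
                  class = c("difference_series", class(tibble::tibble())))
  s <- summarize_risk(ds)
  expect_equal(s$mean, 0.005)
  half <- stats::qt(0.975, 1) * stats::sd(c(0.004, 0.006)) / sqrt(2)
  expect_equal(s$lo, 0.005 - half)
  expect_equal(s$hi, 0.005 + half)
  expect_equal(round(s$hi, 6), 0.017706)

  # constant series: zero-width interval around the constant
  dsc <- structure(tibble::tibble(age = 70:74, diff = rep(0.01, 5)),
                   class = class(ds))
  sc <- summarize_risk(dsc)
  expect_equal(c(sc$lo, sc$mean, sc$hi), rep(0.01, 3))

  # degenerate lengths
  ds1 <- structure(tibble::tibble(age = 70L, diff = 0.2), class = class(ds))
  s1 <- summarize_risk(ds1)
  expect_equal(s1$mean, 0.2)
  expect_true(is.na(s1$lo))
  s0 <- summarize_risk(structure(tibble::tibble(age = integer(),
                                                diff = numeric()),
                                 class = class(ds)))
  expect_true(is.na(s0$mean))
})

test_that("bootstrap interval is seeded, contains the mean, and is sane", {
  set.seed(1)
  ds <- structure(tibble::tibble(age = 65:90, diff = rnorm(26, 0.01, 0.002)),
                  class = c("difference_series", class(tibble::tibble())))
  b1 <- summarize_risk(ds, method = "bootstrap", seed = 5)
  b2 <- summarize_risk(ds, method = "bootstrap", seed = 5)
  expect_identical(b1, b2)
  expect_lte(b1$lo, b1$mean)
  expect_gte(b1$hi, b1$mean)
  tt <- summarize_risk(ds)
  expect_lt(abs(b1$lo - tt$lo), 0.002)
})

test_that("risk table ranks are a permutation within each group", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:80)
  coh <- simulate_oracle_cohort(scn)
  surf <- build_surface(coh, mortality_model_of(scn), "male")
  tab <- marginal_risk_table(surf, "male")
  expect_equal(nrow(tab), 3 * (2^3 / 2 - 1))   # n = 2^m/2 - 1 per target
  for (k in unique(tab$target)) {
    for (nb in unique(tab$n_basic)) {
      r <- tab$rank[tab$target == k & tab$n_basic == nb]
      expect_setequal(r, seq_along(r))
    }
  }
  expect_true(all(tab$lo <= tab$mean & tab$mean <= tab$hi, na.rm = TRUE))
})

test_that("nested chains pick the argmax single disease first", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:80)
  coh <- simulate_oracle_cohort(scn)
  surf <- build_surface(coh, mortality_model_of(scn), "male")
  tab <- marginal_risk_table(surf, "male")
  ch <- max_impact_chain(tab, "A")
  expect_equal(ch$size, 1:2)
  singles <- tab[tab$target == "A" & tab$n_basic == 1, ]
  expect_equal(ch$state[1], singles$state[which.max(singles$mean)])
  # each chain state is nested in the next
  b1 <- comorbidrisk:::as_state_bits(ch$state[1], 3)
  b2 <- comorbidrisk:::as_state_bits(ch$state[2], 3)
  expect_true(all(b2 >= b1))
  expect_equal(sum(b2), 2)
})

test_that("exhaustive chains dominate nested chains at every size", {
  scn <- make_exchangeable_scenario(m = 4, ages = 65:80,
                                    levels = c(0.01, 0.02, 0.05, 0.12))
  coh <- simulate_oracle_cohort(scn)
  surf <- build_surface(coh, mortality_model_of(scn), "male")
  tab <- marginal_risk_table(surf, "male")
  for (k in scn$diseases) {
    nested <- max_impact_chain(tab, k, "nested")
    exhaustive <- max_impact_chain(tab, k, "exhaustive")
    expect_equal(nrow(nested), 3)
    expect_true(all(exhaustive$mean >= nested$mean - 1e-12))
  }
})

test_that("amplification: marginal risk grows with the basic-disease count", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:90)
  coh <- simulate_oracle_cohort(scn)
  surf <- build_surface(coh, mortality_model_of(scn), "male")
  tab <- marginal_risk_table(surf, "male")
  for (k in scn$diseases) {
    ch <- max_impact_chain(tab, k)
    expect_true(all(diff(ch$mean) > 0))
  }
})

test_that("mutual-impact pairs are detected from the single-basic argmaxes", {
  # synthetic risk table: A<->B mutual, C points at B
  tab <- tibble::tibble(
    target = c("A", "A", "B", "B", "C", "C"),
    state = c("010", "001", "100", "001", "100", "010"),
    n_basic = 1L,
    mean = c(0.5, 0.1, 0.6, 0.2, 0.1, 0.4),
    lo = NA_real_, hi = NA_real_, n_ages = 10L, rank = 1L)
  tab <- structure(tab, diseases = c("A", "B", "C"),
                   class = c("marginal_risk_table", class(tibble::tibble())))
  mp <- mutual_impact_pairs(tab)
  expect_equal(nrow(mp), 1)
  expect_setequal(unlist(mp[1, ]), c("A", "B"))

  # chain A->B, B->C, C->B: only (B, C) mutual
  tab$mean <- c(0.5, 0.1, 0.2, 0.6, 0.1, 0.4)
  mp2 <- mutual_impact_pairs(tab)
  expect_equal(nrow(mp2), 1)
  expect_setequal(unlist(mp2[1, ]), c("B", "C"))
})

test_that("series diagnostics report trend and autocorrelation", {
  ds <- structure(tibble::tibble(age = 65:90,
                                 diff = 0.001 * (65:90) - 0.05),
                  class = c("difference_series", class(tibble::tibble())))
  dg <- series_diagnostics(ds)
  expect_equal(dg$trend_slope, 0.001, tolerance = 1e-10)
  expect_gt(dg$lag1_acf, 0.5)
})
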