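test_that("parameter validation rejects invalid fields by name", {
  expect_error(synth_params(n_subjects = 0), "n_subjects")
  expect_error(synth_params(sex_ratio = 1.5), "sex_ratio")
  expect_error(synth_params(disease_names = c("A", "B"),
                            baseline_prevalence = c(-0.1, 0.2),
                            prevalence_age_slope = c(0, 0)),
               "baseline_prevalence")
  expect_error(synth_params(gompertz_a = -1), "gompertz")
  bad <- matrix(0.5, 3, 3)  # nonzero diagonal
  expect_error(synth_params(disease_names = c("A", "B", "C"),
                            baseline_prevalence = rep(0.1, 3),
                            prevalence_age_slope = rep(0, 3),
                            pairwise_log_odds = bad),
               "pairwise_log_odds")
})

test_that("zero-prevalence parameters yield an all-healthy survey", {
  p <- synth_params(n_subjects = 200, age_range = c(65, 70),
                    disease_names = c("A", "B"),
                    baseline_prevalence = c(0, 0),
                    prevalence_age_slope = c(0, 0),
                    pairwise_log_odds = matrix(0, 2, 2), seed = 4)
  sv <- generate_survey(p)
  expect_equal(nrow(sv), 200)
  expect_true(all(sv$A == 0) && all(sv$B == 0))
})

test_that("survey generation is deterministic given the seed", {
  p <- small_params(n = 1000, seed = 99)
  expect_identical(generate_survey(p), generate_survey(p))
})

test_that("ages, sex labels and record count honor the parameters", {
  p <- small_params(n = 2000, seed = 5)
  sv <- generate_survey(p)
  expect_equal(nrow(sv), 2000)
  expect_true(all(sv$age >= 65 & sv$age <= 74))
  expect_true(all(sv$sex %in% c("male", "female")))
  expect_identical(attr(sv, "diseases"), c("A", "B", "C"))
})

test_that("pairwise log-odds of generated indicators match the model", {
  p <- synth_params(n_subjects = 50000, age_range = c(65, 70),
                    disease_names = c("a", "b"),
                    baseline_prevalence = c(0.3, 0.3),
                    prevalence_age_slope = c(0, 0),
                    pairwise_log_odds = matrix(c(0, 1, 1, 0), 2),
                    excess_mortality = c(a = 0.01, b = 0.01), seed = 7)
  sv <- generate_survey(p)
  tab <- table(factor(sv$a, 0:1), factor(sv$b, 0:1))
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]))
  expect_lt(abs(lor - 1), 0.1)
})

test_that("marginal prevalence tracks the age profile within 3 binomial SE", {
  p <- small_params(n = 30000, seed = 21)
  sv <- generate_survey(p)
  for (d in seq_along(p$disease_names)) {
    for (a in 65:74) {
      rows <- sv$age == a
      n_a <- sum(rows)
      tgt <- comorbidrisk:::prevalence_profile(p, a)[d]
      obs <- mean(sv[[p$disease_names[d]]][rows])
      se <- sqrt(tgt * (1 - tgt) / n_a)
      expect_lt(abs(obs - tgt), 3 * se + 1e-12)
    }
  }
})

test_that("Gompertz life table matches its closed form and is monotone", {
  p <- synth_params(gompertz_a = 0.01, gompertz_b = 0.1, seed = 1)
  lt <- generate_lifetable(p)
  expect_equal(lifetable_rate(lt, 65, "male"), 0.01)
  expect_equal(lifetable_rate(lt, 75, "female"), 0.01 * exp(1))
  for (s in c("male", "female")) {
    r <- lt$mortality[lt$sex == s][order(lt$age[lt$sex == s])]
    expect_true(all(diff(r) >= 0))
  }
  p0 <- synth_params(gompertz_a = 0, seed = 1)
  expect_true(all(generate_lifetable(p0)$mortality == 0))
})

test_that("oracle simulation: no flows means constant state counts", {
  dis <- c("A", "B")
  lt <- make_lifetable(65:70, rate = 0)
  scn <- oracle_scenario(dis, 65:70, count_hazard(c(0, 0)),
                         c(100, 20, 30, 5), lt)
  coh <- simulate_oracle_cohort(scn)
  for (ai in seq_along(coh$ages)) {
    expect_equal(unname(coh$counts[ai, , 1]), c(100, 20, 30, 5))
  }
})

test_that("oracle simulation: single-disease onset decays geometrically", {
  lt <- make_lifetable(65:75, rate = 0)
  h <- 0.07
  scn <- oracle_scenario("A", 65:75, count_hazard(h), c(1000, 0), lt)
  coh <- simulate_oracle_cohort(scn)
  k <- seq_along(coh$ages) - 1
  expect_equal(unname(coh$counts[, 1, 1]), 1000 * (1 - h)^k)
})

test_that("oracle simulation conserves counts exactly", {
  scn <- make_exchangeable_scenario()
  coh <- simulate_oracle_cohort(scn)
  deaths <- attr(coh, "deaths")
  tot0 <- colSums(scn$init)
  final <- apply(coh$counts[length(coh$ages), , , drop = FALSE], 3, sum)
  expect_equal(unname(colSums(deaths) + final), unname(tot0),
               tolerance = 1e-12)
  # stepwise: total after a step = total before minus that step's deaths
  for (ai in seq_along(coh$ages)[-1]) {
    expect_equal(sum(coh$counts[ai, , 1]),
                 sum(coh$counts[ai - 1, , 1]) - deaths[ai - 1, 1],
                 tolerance = 1e-9)
  }
})

test_that("oracle simulation rejects hazard + mortality above 1", {
  lt <- make_lifetable(65:67, rate = 0.5)
  scn <- oracle_scenario("A", 65:67, count_hazard(0.6), c(100, 0), lt)
  expect_error(simulate_oracle_cohort(scn), "hazard \\+ mortality")
})
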