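# Cohort with explicit state counts at one or more ages (one sex).
make_cohort <- function(diseases, ages, counts_by_age) {
  m <- length(diseases)
  counts <- array(0, dim = c(length(ages), 2^m, 2))
  for (ai in seq_along(ages)) counts[ai, , 1] <- counts_by_age[[ai]]
  hypothetical_cohort(counts, diseases, ages)
}

test_that("joint tables marginalize states onto the four pair cells", {
  # states over (A,B,C): (0,0,0)=5, (1,0,1)=2, (1,1,0)=3
  cnt <- rep(0, 8)
  cnt[comorbidrisk:::state_index(c(0, 0, 0))] <- 5
  cnt[comorbidrisk:::state_index(c(1, 0, 1))] <- 2
  cnt[comorbidrisk:::state_index(c(1, 1, 0))] <- 3
  coh <- make_cohort(c("A", "B", "C"), 70L, list(cnt))
  jt <- make_joint_tables(coh, "A", "B", "male")
  expect_equal(jt$pop00, 5)
  expect_equal(jt$pop10, 2)
  expect_equal(jt$pop01, 0)
  expect_equal(jt$pop11, 3)
  expect_equal(jt$pop00 + jt$pop10 + jt$pop01 + jt$pop11, sum(cnt))
  expect_error(make_joint_tables(coh, "A", "Z", "male"), "not tracked")
  expect_error(make_joint_tables(coh, "A", "A", "male"), "distinct")
})

test_that("pair-cell mortality follows the additive survivor formula", {
  coh <- make_cohort(c("A", "B"), 70L, list(c(200, 150, 120, 100)))
  lt <- make_lifetable(70, rate = 0.05)
  mm <- mortality_model(lt, c(A = 0.02, B = 0.03))
  jt <- apply_mortality(make_joint_tables(coh, "A", "B", "male"), mm)
  expect_equal(jt$surv00, 200 * 0.95)
  expect_equal(jt$surv10, 150 * 0.93)
  expect_equal(jt$surv01, 120 * 0.92)
  expect_equal(jt$surv11, 100 * 0.90)

  # immortal cohort: survivors equal populations
  mm0 <- mortality_model(make_lifetable(70, rate = 0))
  jt0 <- apply_mortality(make_joint_tables(coh, "A", "B", "male"), mm0)
  expect_equal(jt0$surv11, jt0$pop11)

  # monotone ordering of cell survival fractions
  expect_gte(jt$surv00 / jt$pop00, jt$surv11 / jt$pop11)

  mm_bad <- mortality_model(make_lifetable(70, rate = 0.5),
                            c(A = 0.3, B = 0.3))
  expect_error(apply_mortality(make_joint_tables(coh, "A", "B", "male"),
                               mm_bad), "exceeds 1")
})

test_that("the proportional closure solves the documented flow system", {
  r <- comorbidrisk:::solve_flows(
    pop00 = 1000, pop10 = 100, pop01 = 100,
    surv00 = 1000, surv10 = 100, surv01 = 100,
    pop00_1 = 950, pop10_1 = 120, pop01_1 = 110)
  expect_equal(r$a, 50 * 40 / 70)
  expect_equal(r$b, 50 * 30 / 70)
  expect_equal(r$c_flow, r$a - 20)
  expect_equal(r$d_flow, r$b - 10)
  # the (1,1)-inflow identity holds: c + d = Delta(1,1) = 30 - 10
  expect_equal(r$c_flow + r$d_flow, 20)
  expect_equal(r$rate_i_00, r$a / 1000)
  expect_equal(r$rate_j_10, r$c_flow / 100)
})

test_that("a stationary table (deaths only) produces zero flows", {
  jt_t <- structure(tibble::tibble(
    age = 70L, pop00 = 100, pop10 = 50, pop01 = 40, pop11 = 10,
    surv00 = 95, surv10 = 45, surv01 = 36, surv11 = 9),
    pair = c("A", "B"), sex = "male",
    class = c("joint_table", class(tibble::tibble())))
  jt_t1 <- structure(tibble::tibble(
    age = 71L, pop00 = 95, pop10 = 45, pop01 = 36, pop11 = 9),
    pair = c("A", "B"), sex = "male",
    class = c("joint_table", class(tibble::tibble())))
  fl <- pairwise_flows(jt_t, jt_t1)
  expect_equal(fl$a, 0)
  expect_equal(fl$b, 0)
  expect_equal(fl$c_flow, 0)
  expect_equal(fl$d_flow, 0)
})

test_that("negative implied flows are clipped and empty cells flagged", {
  r <- comorbidrisk:::solve_flows(
    pop00 = 100, pop10 = 0, pop01 = 10,
    surv00 = 100, surv10 = 0, surv01 = 10,
    pop00_1 = 105, pop10_1 = 0, pop01_1 = 10)  # prevalence dip
  expect_equal(r$a, 0)
  expect_equal(r$b, 0)
  expect_gt(r$clipped, 0)
  expect_true(is.na(r$rate_j_10))  # empty (1,0) source cell
})

test_that("conditional incidence is the population-weighted average", {
  expect_equal(conditional_incidence(c(0.02, 0.04), c(300, 100)), 0.025)
  expect_equal(conditional_incidence(0.07, 123), 0.07)      # m = 2 case
  expect_equal(conditional_incidence(c(0.03, 0.03, 0.03), c(1, 50, 7)), 0.03)
  expect_equal(conditional_incidence(c(0.02, NA), c(10, 99)), 0.02)
  expect_true(is.na(conditional_incidence(c(NA_real_, NA_real_), c(1, 1))))
})

test_that("the surface enumerates 2^(m-1) states per target", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:70)
  coh <- simulate_oracle_cohort(scn)
  surf <- build_surface(coh, mortality_model_of(scn), "male")
  # union over targets: every 3-bit state with at least one 0 bit
  expect_equal(length(unique(surf$state)), 7)
  for (k in scn$diseases) {
    sk <- surf[surf$target == k, ]
    expect_equal(length(unique(sk$state)), 4)   # 2^(3-1)
    expect_true(all(substr(sk$state, match(k, scn$diseases),
                           match(k, scn$diseases)) == "0"))
  }
  expect_true(all(surf$incidence[!surf$flagged] >= 0 &
                    surf$incidence[!surf$flagged] <= 1))
})

test_that("flows recover oracle hazards exactly under the matched closure", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:90)
  coh <- simulate_oracle_cohort(scn)
  mm <- mortality_model_of(scn)
  surf <- build_surface(coh, mm, "male")
  est <- attr(surf, "pairwise")
  tru <- true_pairwise_rates(scn, coh)
  j <- merge(as.data.frame(est), as.data.frame(tru),
             by = c("sex", "age", "target", "partner", "d_partner"))
  j <- j[j$sex == "male", ]
  expect_equal(nrow(j), 3 * 2 * 2 * 25)
  expect_lt(max(abs(j$rate.x - j$rate.y)), 1e-8)

  # Eq-5 aggregation of the true pairwise rates matches the surface
  for (age in c(65, 75, 88)) {
    for (k in scn$diseases) {
      others <- setdiff(scn$diseases, k)
      for (s in 0:3) {
        bits_partners <- as.integer(intToBits(s))[1:2]
        tr <- mapply(function(l, dl) {
          row <- tru[tru$sex == "male" & tru$age == age & tru$target == k &
                       tru$partner == l & tru$d_partner == dl, ]
          c(row$rate, row$pop)
        }, others, bits_partners)
        want <- conditional_incidence(tr[1, ], tr[2, ])
        bits_full <- integer(3)
        bits_full[match(others, scn$diseases)] <- bits_partners
        got <- surf$incidence[surf$sex == "male" & surf$age == age &
                                surf$target == k &
                                surf$state == comorbidrisk:::state_bitstring(bits_full)]
        expect_equal(got, want, tolerance = 1e-8)
      }
    }
  }
})

test_that("pair-level mortality carries the expected marginalization bias", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:90)
  coh <- simulate_oracle_cohort(scn)
  mm <- mortality_model_of(scn)
  tru <- true_pairwise_rates(scn, coh)
  surf_pair <- build_surface(coh, mm, "male", mortality = "pair")
  est <- attr(surf_pair, "pairwise")
  j <- merge(as.data.frame(est), as.data.frame(tru),
             by = c("sex", "age", "target", "partner", "d_partner"))
  err <- max(abs(j$rate.x - j$rate.y), na.rm = TRUE)
  # biased, but bounded by the out-of-pair excess-mortality mass:
  # at most (excess rate) x (max out-of-pair prevalence share) + slack
  expect_gt(err, 1e-8)
  expect_lt(err, max(scn$excess))
})

test_that("count conservation holds through the flow decomposition", {
  scn <- make_exchangeable_scenario(m = 3, ages = 65:80)
  coh <- simulate_oracle_cohort(scn)
  mm <- mortality_model_of(scn)
  sv <- comorbidrisk:::survivors_state(coh, mm, "male")
  for (ai in seq_along(coh$ages)[-length(coh$ages)]) {
    expect_equal(sum(coh$counts[ai + 1, , 1]), sum(sv[ai, ]),
                 tolerance = 1e-9)
  }
})
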