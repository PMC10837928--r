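#' Oracle scenario for parameter-recovery tests
#'
#' Bundles the ground truth of a forward simulation: the tracked diseases,
#' the age axis, per-state one-year onset hazards, the initial population
#' per joint disease state, a life table supplying base mortality, and
#' per-disease additive excess mortality. The hazard is a function
#' `hazard(disease, state, sex, age)` returning the true one-year onset
#' probability of `disease` for an individual currently in joint `state`
#' (a named 0/1 vector over all diseases, with `state[disease] == 0`).
#'
#' @param diseases disease labels.
#' @param ages integer age axis (annual steps from the first age).
#' @param hazard hazard function as described above; see [count_hazard()]
#'   for a convenient superadditive form.
#' @param init initial population at the first age: numeric vector of
#'   length `2^m` (state-indexed, little-endian) used for every sex, or a
#'   `2^m x n_sexes` matrix.
#' @param lifetable a `life_table` covering `ages` for all `sexes`.
#' @param excess_mortality named per-disease numeric vector (recycled to
#'   both sexes), or `NULL` for none.
#' @param sexes sex strata to simulate.
#' @return an object of class `oracle_scenario`.
#' @export
oracle_scenario <- function(diseases, ages, hazard, init, lifetable,
                            excess_mortality = NULL,
                            sexes = c("male", "female")) {
  m <- length(diseases)
  init <- if (is.matrix(init)) init else
    matrix(init, nrow = 2^m, ncol = length(sexes))
  stopifnot(nrow(init) == 2^m, ncol(init) == length(sexes))
  if (any(init < 0)) stop("initial populations must be non-negative",
                          call. = FALSE)
  ex <- stats::setNames(rep(0, m), diseases)
  if (!is.null(excess_mortality)) {
    stopifnot(all(names(excess_mortality) %in% diseases))
    ex[names(excess_mortality)] <- excess_mortality
  }
  check_prob(ex, "excess_mortality")
  structure(list(diseases = diseases, ages = as.integer(ages),
                 hazard = hazard, init = init,
                 lifetable = new_lifetable(lifetable),
                 excess = ex, sexes = sexes),
            class = "oracle_scenario")
}

#' Superadditive count-dependent hazard
#'
#' Returns a hazard function for [oracle_scenario()] in which the onset
#' probability of every disease depends only on how many other diseases
#' the individual already has: `levels[1]` from full health, `levels[2]`
#' with one existing disease, and so on. Increasing, convex `levels`
#' encode the mutual-amplification effect the comorbidity analysis is
#' meant to detect; identical levels across diseases make the scenario
#' exchangeable, which is the regime where the pairwise flow closure is
#' exact.
#'
#' @param levels numeric vector of onset probabilities by current disease
#'   count (length at least m).
#' @param age_factor optional multiplier applied as
#'   `age_factor^(age - min_age)`; default 1 (age-constant hazards).
#' @param min_age age at which the factor is 1.
#' @return a `hazard(disease, state, sex, age)` function.
#' @export
count_hazard <- function(levels, age_factor = 1, min_age = 65) {
  force(levels); force(age_factor); force(min_age)
  function(disease, state, sex, age) {
    levels[sum(state) + 1] * age_factor^(age - min_age)
  }
}

#' Forward-simulate an oracle cohort with known hazards
#'
#' Deterministic expected-count simulation: at each annual step, every
#' joint state loses deaths (base mortality plus the sum of its diseases'
#' excess mortality) and onset flows (one per absent disease, at the true
#' hazard), both computed from the start-of-interval state population;
#' onset flows enter the state with the extra disease. Diseases are
#' absorbing. A step in which deaths plus onsets exceed the cell
#' population signals `hazard + mortality > 1` and raises an error.
#'
#' @param scn an [oracle_scenario()].
#' @return a [hypothetical_cohort()] holding the state-count surface by
#'   age, with attribute `deaths` (an age-by-sex matrix of expected deaths
#'   during each interval) for conservation checks.
#' @export
simulate_oracle_cohort <- function(scn) {
  stopifnot(inherits(scn, "oracle_scenario"))
  m <- length(scn$diseases)
  S <- state_matrix(m)
  n_states <- nrow(S)
  ages <- scn$ages
  counts <- array(0, dim = c(length(ages), n_states, length(scn$sexes)))
  deaths <- matrix(0, length(ages), length(scn$sexes),
                   dimnames = list(ages, scn$sexes))
  state_excess <- as.vector(S %*% scn$excess)
  # target state index when disease d onsets from state s (NA if d present)
  onset_target <- outer(seq_len(n_states), seq_len(m), function(s, d) {
    s + 2^(d - 1) * (1 - S[cbind(s, d)])
  })
  for (si in seq_along(scn$sexes)) {
    sex <- scn$sexes[si]
    pop <- scn$init[, si]
    counts[1, , si] <- pop
    for (ai in seq_along(ages)[-length(ages)]) {
      age <- ages[ai]
      death_rate <- lifetable_rate(scn$lifetable, age, sex) + state_excess
      H <- matrix(0, n_states, m)
      for (s in seq_len(n_states)) {
        for (d in seq_len(m)) {
          if (S[s, d] == 0) {
            H[s, d] <- scn$hazard(scn$diseases[d], S[s, ],
                                  sex, age)
          }
        }
      }
      check_prob(H, "hazard")
      remain <- pop * (1 - death_rate - rowSums(H))
      if (any(remain < -1e-9)) {
        bad <- which(remain < -1e-9)[1]
        stop(sprintf(
          "negative count in state %s at age %d (%s): hazard + mortality > 1",
          state_bitstring(S[bad, ]), age, sex), call. = FALSE)
      }
      remain[remain < 0] <- 0
      flows <- pop * H
      nxt <- remain
      for (d in seq_len(m)) {
        from <- which(S[, d] == 0)
        tgt <- onset_target[from, d]
        nxt[tgt] <- nxt[tgt] + flows[from, d]
      }
      deaths[ai, si] <- sum(pop * death_rate)
      pop <- nxt
      counts[ai + 1, , si] <- pop
    }
  }
  out <- hypothetical_cohort(counts, scn$diseases, ages, scn$sexes,
                             anchor_age = min(ages))
  attr(out, "deaths") <- deaths
  out
}

#' True pairwise onset rates of an oracle scenario
#'
#' Forward-knowledge truth for recovery tests: for each target disease
#' `k`, partner `l`, partner status `d_l` and age, the exact one-year
#' onset rate of `k` out of the pair cell `(d_k = 0, d_l)` is the
#' hazard-weighted average `sum over states in the cell of
#' hazard_k(state) * pop(state) / cell population`. Computed directly
#' from the scenario's hazard function and the simulated state surface --
#' it never touches the transition estimator.
#'
#' @param scn the [oracle_scenario()].
#' @param cohort the cohort returned by [simulate_oracle_cohort()].
#' @return tibble: `sex`, `age`, `target`, `partner`, `d_partner`, `rate`,
#'   `pop` (the cell population the rate refers to).
#' @export
true_pairwise_rates <- function(scn, cohort) {
  m <- length(scn$diseases)
  S <- cohort$states
  res <- list()
  for (si in seq_along(scn$sexes)) {
    sex <- scn$sexes[si]
    for (ai in seq_along(cohort$ages)[-length(cohort$ages)]) {
      age <- cohort$ages[ai]
      pop <- cohort$counts[ai, , si]
      hz <- matrix(0, nrow(S), m)
      for (s in seq_len(nrow(S))) {
        for (d in seq_len(m)) {
          if (S[s, d] == 0) {
            hz[s, d] <- scn$hazard(scn$diseases[d], S[s, ], sex, age)
          }
        }
      }
      for (k in seq_len(m)) {
        for (l in seq_len(m)) {
          if (l == k) next
          for (dl in 0:1) {
            cell <- S[, k] == 0 & S[, l] == dl
            tot <- sum(pop[cell])
            rate <- if (tot > 0) sum(hz[cell, k] * pop[cell]) / tot else NA_real_
            res[[length(res) + 1]] <- tibble::tibble(
              sex = sex, age = age,
              target = scn$diseases[k], partner = scn$diseases[l],
              d_partner = dl, rate = rate, pop = tot)
          }
        }
      }
    }
  }
  dplyr::bind_rows(res)
}
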