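# Shared fixture builders; everything is generated in code.

# Flat or Gompertz life table over an age range, same for both sexes.
make_lifetable <- function(ages, rate = 0, a = NULL, b = NULL) {
  mort <- if (is.null(a)) rep(rate, length(ages)) else
    pmin(1, a * exp(b * (ages - min(ages))))
  comorbidrisk:::new_lifetable(data.frame(
    age = rep(ages, 2), sex = rep(c("male", "female"), each = length(ages)),
    mortality = rep(mort, 2)))
}

# Minimal population series from explicit counts (one sex).
make_popseries <- function(ages, observed, sex = "male", anchor = min(ages)) {
  structure(tibble::tibble(age = as.integer(ages), sex = sex,
                           observed = observed),
            anchor_age = as.integer(anchor),
            class = c("population_series", class(tibble::tibble())))
}

# Exchangeable superadditive oracle scenario: identical count-dependent
# hazards, identical excess mortality and permutation-symmetric initial
# populations, so the proportional flow closure is exact.
make_exchangeable_scenario <- function(m = 3, ages = 65:90,
                                       levels = c(0.01, 0.03, 0.08, 0.2),
                                       age_factor = 1.02,
                                       gompertz = c(0.01, 0.08),
                                       excess = 0.02,
                                       n0 = 10000) {
  dis <- LETTERS[seq_len(m)]
  lt <- make_lifetable(ages, a = gompertz[1], b = gompertz[2])
  S <- comorbidrisk:::state_matrix(m)
  # symmetric start: population depends on disease count only
  init <- n0 * 0.05^rowSums(S)
  init[1] <- n0
  oracle_scenario(dis, ages, count_hazard(levels[seq_len(m)], age_factor),
                  init, lt,
                  excess_mortality = stats::setNames(rep(excess, m), dis))
}

mortality_model_of <- function(scn) {
  mortality_model(scn$lifetable, scn$excess)
}

# Published weighted-degree table shipped with the package.
published_degrees <- function() {
  utils::read.csv(system.file("extdata", "clhls2018_weighted_degrees.csv",
                              package = "comorbidrisk"),
                  check.names = FALSE)
}

published_counts <- function() {
  utils::read.csv(system.file("extdata", "clhls2018_baseline_counts.csv",
                              package = "comorbidrisk"),
                  check.names = FALSE)
}

# Tiny three-disease survey parameters used across tests.
small_params <- function(n = 5000, seed = 1, J = 0.8, ages = c(65, 74)) {
  m <- 3
  Jm <- matrix(J, m, m); diag(Jm) <- 0
  synth_params(n_subjects = n, age_range = ages,
               disease_names = c("A", "B", "C"),
               baseline_prevalence = c(0.25, 0.15, 0.10),
               prevalence_age_slope = c(0.01, 0.008, 0.005),
               pairwise_log_odds = Jm,
               excess_mortality = c(A = 0.02, B = 0.02, C = 0.02),
               seed = seed)
}
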