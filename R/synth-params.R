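#' The 16 chronic diseases tracked in the CLHLS 2017-2018 survey wave
#'
#' @return character vector of 16 disease labels, in the conventional order.
#' @export
clhls_diseases <- function() {
  c("hypertension", "diabetes", "heart disease", "stroke",
    "chronic lung disease", "cancer", "chronic stomach disease",
    "parkinson's disease", "arthritis", "dementia", "epilepsy",
    "cholelith disease", "dyslipidemia", "rheumatism",
    "chronic nephritis", "chronic hepatitis")
}

# Published overall prevalence (proportion of the 12,139 respondents) per
# disease in the 2017-2018 wave; anchors the generator's default
# age-prevalence profiles.
clhls_overall_prevalence <- function() {
  stats::setNames(
    c(0.3958, 0.0888, 0.1624, 0.1071, 0.1011, 0.0140, 0.0444, 0.0072,
      0.1012, 0.0216, 0.0024, 0.0381, 0.0484, 0.0492, 0.0107, 0.0042),
    clhls_diseases())
}

# The seven diseases with above-average comorbidity degree in elderly men;
# the generator's default pairwise associations are stronger among them.
clhls_major_diseases <- function() {
  c("hypertension", "diabetes", "heart disease", "stroke",
    "chronic lung disease", "arthritis", "dyslipidemia")
}

#' Parameters of the synthetic survey generator
#'
#' Bundles and validates every knob of the synthetic cross-sectional survey:
#' sample size, age range (the last age is an open "and older" band), sex
#' ratio, the tracked disease list, each disease's prevalence at the anchor
#' age plus a linear per-year increase, a symmetric matrix of pairwise
#' log-odds associations (the disease indicators follow a pairwise
#' log-linear model), Gompertz base-mortality parameters
#' (hazard `a * exp(b * (age - 65))`), and additive per-disease excess
#' annual death probabilities.
#'
#' Defaults emulate the CLHLS 2017-2018 wave: ~12,000 respondents aged
#' 65-105+, 44.58% male, the 16 tracked chronic diseases with
#' age-increasing prevalence anchored on the wave's published overall
#' proportions, and stronger pairwise association among the seven
#' high-comorbidity diseases.
#'
#' @param n_subjects number of survey records.
#' @param age_range integer length-2, closed age interval; the upper age
#'   collapses everyone older into one band.
#' @param sex_ratio proportion male in `[0, 1]`.
#' @param disease_names ordered, duplicate-free disease labels.
#' @param baseline_prevalence per-disease prevalence at the youngest age.
#' @param prevalence_age_slope per-disease additive prevalence increase per
#'   year of age (profile clipped to `[0, 1]`).
#' @param pairwise_log_odds symmetric zero-diagonal matrix of pairwise
#'   log-odds between disease indicators.
#' @param gompertz_a,gompertz_b base-mortality parameters; scalars or
#'   named length-2 vectors `c(male = , female = )`.
#' @param excess_mortality per-disease additive annual death probability.
#' @param seed integer random seed.
#' @return a validated list of class `synth_params`.
#' @export
synth_params <- function(n_subjects = 12000L,
                         age_range = c(65L, 105L),
                         sex_ratio = 0.4458,
                         disease_names = clhls_diseases(),
                         baseline_prevalence = NULL,
                         prevalence_age_slope = NULL,
                         pairwise_log_odds = NULL,
                         gompertz_a = 0.015,
                         gompertz_b = 0.095,
                         excess_mortality = NULL,
                         seed = 1L) {
  # config files (YAML/JSON) deliver vectors as lists and matrices as
  # lists of rows; coerce before validating
  if (is.list(excess_mortality)) excess_mortality <- unlist(excess_mortality)
  if (is.list(baseline_prevalence)) baseline_prevalence <- unlist(baseline_prevalence)
  if (is.list(prevalence_age_slope)) prevalence_age_slope <- unlist(prevalence_age_slope)
  if (is.list(gompertz_a)) gompertz_a <- unlist(gompertz_a)
  if (is.list(gompertz_b)) gompertz_b <- unlist(gompertz_b)
  if (is.list(pairwise_log_odds)) {
    pairwise_log_odds <- do.call(rbind, lapply(pairwise_log_odds, unlist))
  }
  if (is.list(disease_names)) disease_names <- unlist(disease_names)
  if (is.list(age_range)) age_range <- unlist(age_range)
  if (length(n_subjects) != 1 || !is.finite(n_subjects) || n_subjects < 1) {
    stop("field 'n_subjects' must be a single count >= 1", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  age_range <- as.integer(age_range)
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    stop("field 'age_range' must be an ordered integer pair", call. = FALSE)
  }
  check_prob(sex_ratio, "sex_ratio")
  if (length(disease_names) == 0 || anyDuplicated(disease_names)) {
    stop("field 'disease_names' must be non-empty and duplicate-free",
         call. = FALSE)
  }
  m <- length(disease_names)

  if (is.null(baseline_prevalence) || is.null(prevalence_age_slope)) {
    ov <- clhls_overall_prevalence()
    if (!all(disease_names %in% names(ov))) {
      stop("baseline_prevalence and prevalence_age_slope are required for ",
           "non-default disease lists", call. = FALSE)
    }
    ov <- ov[disease_names]
    # Anchor below the overall proportion and let prevalence drift up with
    # age, so that the cross-sectional mean lands near the published value.
    baseline_prevalence <- baseline_prevalence %||% unname(0.8 * ov)
    prevalence_age_slope <- prevalence_age_slope %||% unname(0.01 * ov)
  }
  baseline_prevalence <- rep_len(baseline_prevalence, m)
  prevalence_age_slope <- rep_len(prevalence_age_slope, m)
  check_prob(baseline_prevalence, "baseline_prevalence")
  if (any(!is.finite(prevalence_age_slope))) {
    stop("field 'prevalence_age_slope' must be finite", call. = FALSE)
  }

  if (is.null(pairwise_log_odds)) {
    pairwise_log_odds <- matrix(0.1, m, m)
    major <- which(disease_names %in% clhls_major_diseases())
    pairwise_log_odds[major, major] <- 0.4
    diag(pairwise_log_odds) <- 0
  }
  pairwise_log_odds <- as.matrix(pairwise_log_odds)
  if (!all(dim(pairwise_log_odds) == c(m, m)) ||
      any(!is.finite(pairwise_log_odds)) ||
      max(abs(pairwise_log_odds - t(pairwise_log_odds))) > 1e-12 ||
      any(abs(diag(pairwise_log_odds)) > 1e-12)) {
    stop("field 'pairwise_log_odds' must be a symmetric ", m, "x", m,
         " matrix with zero diagonal", call. = FALSE)
  }

  gompertz_a <- expand_by_sex(gompertz_a, "gompertz_a")
  gompertz_b <- expand_by_sex(gompertz_b, "gompertz_b")
  if (any(gompertz_a < 0) || any(gompertz_b < 0)) {
    stop("fields 'gompertz_a' and 'gompertz_b' must be non-negative",
         call. = FALSE)
  }

  if (is.null(excess_mortality)) {
    excess_mortality <- stats::setNames(rep(0.01, m), disease_names)
    bump <- c("cancer" = 0.08, "stroke" = 0.04, "dementia" = 0.04,
              "heart disease" = 0.03, "chronic lung disease" = 0.03,
              "chronic nephritis" = 0.03, "diabetes" = 0.02)
    hit <- intersect(names(bump), disease_names)
    excess_mortality[hit] <- bump[hit]
  }
  if (!is.null(names(excess_mortality))) {
    if (!all(disease_names %in% names(excess_mortality))) {
      stop("field 'excess_mortality' is missing diseases", call. = FALSE)
    }
    excess_mortality <- excess_mortality[disease_names]
  } else {
    excess_mortality <- stats::setNames(rep_len(excess_mortality, m),
                                        disease_names)
  }
  check_prob(excess_mortality, "excess_mortality")

  structure(list(
    n_subjects = n_subjects, age_range = age_range, sex_ratio = sex_ratio,
    disease_names = disease_names,
    baseline_prevalence = baseline_prevalence,
    prevalence_age_slope = prevalence_age_slope,
    pairwise_log_odds = pairwise_log_odds,
    gompertz_a = gompertz_a, gompertz_b = gompertz_b,
    excess_mortality = excess_mortality,
    seed = as.integer(seed)
  ), class = "synth_params")
}

expand_by_sex <- function(x, field) {
  if (length(x) == 1) return(c(male = unname(x), female = unname(x)))
  if (length(x) == 2 && all(c("male", "female") %in% names(x))) {
    return(x[c("male", "female")])
  }
  stop(sprintf("field '%s' must be a scalar or a named male/female pair",
               field), call. = FALSE)
}

# Target marginal prevalence of each disease at a given age.
prevalence_profile <- function(params, age) {
  pmin(1, pmax(0, params$baseline_prevalence +
                 params$prevalence_age_slope * (age - params$age_range[1])))
}
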