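#' Generate a synthetic cross-sectional chronic-disease survey
#'
#' Draws `n_subjects` records with age uniform over the configured range,
#' sex Bernoulli(`sex_ratio`), and disease indicators from a pairwise
#' log-linear (Ising-type) model: within each age, the joint distribution
#' of the 0/1 indicators is proportional to
#' `exp(sum(theta * x) + sum_{d<e} J[d,e] * x[d] * x[e])`, so every
#' pairwise log-odds ratio equals the corresponding `pairwise_log_odds`
#' entry exactly, while the main effects `theta` are calibrated (exact
#' fixed point on the enumerated state space) so that each disease's
#' marginal prevalence matches `baseline + slope * (age - 65)` clipped to
#' `[0, 1]`. Sampling uses per-subject Gibbs sweeps with a fixed burn-in
#' of 50 sweeps from an independence start. Deterministic given
#' `params$seed`.
#'
#' @param params a [synth_params()] object.
#' @return a tibble of class `survey_dataset` with columns `id`, `age`,
#'   `sex`, and one 0/1 column per disease; the disease list is attached
#'   as attribute `diseases`.
#' @export
generate_survey <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  ages <- sample(seq(params$age_range[1], params$age_range[2]), n,
                 replace = TRUE)
  sex <- ifelse(stats::runif(n) < params$sex_ratio, "male", "female")
  X <- sample_disease_indicators(ages, params)
  out <- tibble::tibble(id = seq_len(n), age = ages, sex = sex)
  for (d in seq_along(params$disease_names)) {
    out[[params$disease_names[d]]] <- X[, d]
  }
  new_survey(out, params$disease_names)
}

new_survey <- function(df, diseases) {
  structure(df, diseases = diseases,
            class = c("survey_dataset", class(tibble::as_tibble(df))))
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset: %d records, %d diseases>\n",
              nrow(x), length(attr(x, "diseases"))))
  NextMethod()
}

survey_diseases <- function(survey) {
  attr(survey, "diseases") %||%
    setdiff(names(survey), c("id", "age", "sex"))
}

# Gibbs sampler for the pairwise log-linear indicator model, vectorized
# across subjects. Diseases with degenerate target prevalence (0 or 1) are
# held fixed and contribute their coupling as a field offset.
sample_disease_indicators <- function(ages, params, burn_in = 50L) {
  m <- length(params$disease_names)
  n <- length(ages)
  J <- params$pairwise_log_odds
  uages <- sort(unique(ages))
  pi_t <- t(vapply(uages, function(a) prevalence_profile(params, a),
                   numeric(m)))          # n_uages x m targets
  age_idx <- match(ages, uages)

  X <- matrix(0L, n, m)
  free <- which(apply(pi_t, 2, function(p) any(p > 0 & p < 1)))
  fixed_one <- which(apply(pi_t, 2, function(p) all(p == 1)))
  if (length(fixed_one)) X[, fixed_one] <- 1L
  if (length(free) == 0) return(X)

  # Per-age main effects calibrated so enumerated marginals hit the target.
  # Ages sharing the full free set are calibrated jointly (one matrix
  # product per fixed-point iteration covers all of them).
  theta <- matrix(-Inf, length(uages), m)
  off_full <- if (length(fixed_one)) {
    colSums(matrix(J[fixed_one, free, drop = FALSE],
                   nrow = length(fixed_one)))
  } else rep(0, length(free))
  regular <- which(apply(pi_t[, free, drop = FALSE], 1,
                         function(p) all(p > 0 & p < 1)))
  if (length(regular)) {
    theta[regular, free] <- calibrate_theta(
      pi_t[regular, free, drop = FALSE], J[free, free, drop = FALSE],
      offset = off_full)
  }
  for (ai in setdiff(seq_along(uages), regular)) {
    fr <- free[pi_t[ai, free] > 0 & pi_t[ai, free] < 1]
    off <- if (length(fixed_one)) {
      colSums(matrix(J[fixed_one, fr, drop = FALSE],
                     nrow = length(fixed_one)))
    } else rep(0, length(fr))
    if (length(fr)) {
      theta[ai, fr] <- calibrate_theta(
        matrix(pi_t[ai, fr], nrow = 1), J[fr, fr, drop = FALSE],
        offset = off)
    }
  }

  # Independence start at the target marginals, then fixed burn-in sweeps.
  for (d in free) {
    p0 <- pi_t[cbind(age_idx, d)]
    X[, d] <- as.integer(stats::runif(n) < p0)
  }
  for (s in seq_len(burn_in)) {
    for (d in free) {
      th <- theta[cbind(age_idx, d)]
      field <- th + as.vector(X %*% J[, d])
      draw <- as.integer(stats::runif(n) < stats::plogis(field))
      draw[!is.finite(th)] <- X[!is.finite(th), d]  # degenerate at this age
      X[, d] <- draw
    }
  }
  X
}

# Exact fixed-point calibration of Ising main effects on the enumerated
# state space: theta <- theta + logit(target) - logit(model marginal).
# pi_target is a matrix (one row per age band); all rows are iterated
# jointly so each step is a single matrix product over the state space.
calibrate_theta <- function(pi_target, J, offset = 0,
                            tol = 1e-10, max_iter = 200L) {
  pi_target <- as.matrix(pi_target)
  f <- ncol(pi_target)
  if (f > 20) stop("exact calibration supports at most 20 free diseases",
                   call. = FALSE)
  S <- state_matrix(f)
  pair_energy <- rowSums((S %*% J) * S) / 2
  logit_t <- stats::qlogis(pi_target)
  theta <- logit_t  # independence start
  active <- seq_len(nrow(theta))
  for (it in seq_len(max_iter)) {
    E <- S %*% t(theta[active, , drop = FALSE] +
                   rep(offset, each = length(active))) + pair_energy
    E <- exp(sweep(E, 2, apply(E, 2, max)))
    P <- sweep(E, 2, colSums(E), `/`)
    marg <- t(crossprod(S, P))                # |active| x f
    err <- abs(marg - pi_target[active, , drop = FALSE])
    theta[active, ] <- theta[active, , drop = FALSE] +
      logit_t[active, , drop = FALSE] -
      stats::qlogis(pmin(pmax(marg, 1e-12), 1 - 1e-12))
    active <- active[apply(err, 1, max) >= tol]
    if (length(active) == 0) break
  }
  # The sampler adds couplings to fixed indicators through X %*% J, so the
  # offset is not folded into the returned main effects.
  theta
}

#' Write / read a survey CSV
#'
#' Columns `id`, `age`, `sex`, then one 0/1 column per disease; UTF-8 with
#' a header row.
#'
#' @param survey a `survey_dataset`.
#' @param path file path.
#' @return `read_survey_csv` returns a `survey_dataset`.
#' @export
write_survey_csv <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  new_survey(tibble::as_tibble(df), setdiff(names(df), c("id", "age", "sex")))
}
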