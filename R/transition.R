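#' Joint 2x2 prevalence tables for a disease pair along the age axis
#'
#' For each age, the four `(d_i, d_j)` cell populations of the
#' hypothetical cohort, marginalized over every other tracked disease.
#' Consecutive ages form the estimation pairs of the discrete-time
#' transition model.
#'
#' @param cohort a `hypothetical_cohort`.
#' @param i,j two distinct tracked diseases.
#' @param sex stratum.
#' @return tibble of class `joint_table` with columns `age`, `pop00`,
#'   `pop10`, `pop01`, `pop11` (`pop10` is `d_i = 1, d_j = 0`); the pair
#'   and sex ride along as attributes.
#' @export
make_joint_tables <- function(cohort, i, j, sex) {
  check_sex(sex)
  jt <- cohort_pair_pops(cohort, i, j, sex)
  structure(jt, pair = c(i, j), sex = sex,
            class = c("joint_table", class(tibble::tibble())))
}

#' Apply base and excess mortality to a joint table (pair-cell form)
#'
#' Fills the survivor cells from the literal pair-level formula:
#' `surv(0,0) = pop(0,0) * (1 - a_base)`,
#' `surv(1,0) = pop(1,0) * (1 - a_base - a_i)`,
#' `surv(0,1) = pop(0,1) * (1 - a_base - a_j)`,
#' `surv(1,1) = pop(1,1) * (1 - a_base - a_i - a_j)`,
#' with additive per-disease excess mortality. Note this form ignores
#' excess mortality of diseases outside the pair carried by individuals
#' inside a cell; [build_surface()] defaults to joint-state-resolution
#' survivors instead, which apply the additive rule over each
#' individual's full disease set (see that function's `mortality`
#' argument).
#'
#' @param jt a `joint_table` from [make_joint_tables()].
#' @param mm a `mortality_model`.
#' @return the `joint_table` with `surv00`, `surv10`, `surv01`, `surv11`
#'   columns filled.
#' @export
apply_mortality <- function(jt, mm) {
  pair <- attr(jt, "pair")
  sex <- attr(jt, "sex")
  ab <- alpha_base(mm, jt$age, sex)
  ai <- alpha_excess(mm, pair[1], sex)
  aj <- alpha_excess(mm, pair[2], sex)
  rates <- cbind(ab, ab + ai, ab + aj, ab + ai + aj)
  if (any(rates > 1 + 1e-12)) {
    bad <- which(rates > 1 + 1e-12, arr.ind = TRUE)[1, ]
    cellname <- c("(0,0)", "(1,0)", "(0,1)", "(1,1)")[bad[2]]
    stop(sprintf("death probability exceeds 1 in cell %s at age %d",
                 cellname, jt$age[bad[1]]), call. = FALSE)
  }
  jt$surv00 <- unname(jt$pop00 * (1 - rates[, 1]))
  jt$surv10 <- unname(jt$pop10 * (1 - rates[, 2]))
  jt$surv01 <- unname(jt$pop01 * (1 - rates[, 3]))
  jt$surv11 <- unname(jt$pop11 * (1 - rates[, 4]))
  jt
}

# Joint-state-resolution survivors: ages x states matrix for one sex,
# applying base + sum-of-excess mortality to each full disease state.
survivors_state <- function(cohort, mm, sex) {
  si <- match(sex, cohort$sexes)
  ab <- alpha_base(mm, cohort$ages, sex)
  ex <- alpha_excess(mm, cohort$diseases, sex)
  state_excess <- as.vector(cohort$states %*% ex)
  rate <- outer(ab, state_excess, `+`)
  if (any(rate > 1 + 1e-12)) {
    bad <- which(rate > 1 + 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("death probability exceeds 1 in state %s at age %d",
                 dimnames(cohort$counts)[[2]][bad[2]],
                 cohort$ages[bad[1]]), call. = FALSE)
  }
  cnt <- cohort$counts[, , si, drop = FALSE]
  dim(cnt) <- dim(cohort$counts)[1:2]
  cnt * (1 - rate)
}

# Marginalize a state-resolution survivor matrix into pair cells.
pair_cells_from_states <- function(M, states, di, dj) {
  bi <- states[, di]
  bj <- states[, dj]
  cell <- function(a, b) rowSums(M[, bi == a & bj == b, drop = FALSE])
  list(c00 = cell(0, 0), c10 = cell(1, 0), c01 = cell(0, 1),
       c11 = cell(1, 1))
}

#' Solve one step of the pairwise flow system
#'
#' Between consecutive ages the four onset flows of a 2x2 joint table are
#' under-determined by one degree of freedom: the balance of the healthy
#' cell only gives the sum of the two onsets out of `(0,0)`. The system is
#' closed by splitting that sum in proportion to the marginal
#' (collapsed single-disease) onset counts of `i` and `j`, which the data
#' identify uniquely; the comorbid onsets then follow from the `(1,0)`
#' and `(0,1)` balances, and the `(1,1)` inflow identity holds by
#' construction. Negative solved flows (sampling noise, non-monotone
#' prevalence) are clipped to 0 and flagged; rates divide each flow by
#' its source cell's start-of-interval population and are flagged missing
#' when that population is empty.
#'
#' @param jt_t one-age `joint_table` with survivor columns filled (see
#'   [apply_mortality()]).
#' @param jt_t1 the next age's `joint_table` (populations only needed).
#' @return a list of class `pairwise_flows`: onset counts `a` (i from
#'   healthy), `b` (j from healthy), `c_flow` (j from `(1,0)`), `d_flow`
#'   (i from `(0,1)`), the four corresponding rates, and flag counters.
#' @export
pairwise_flows <- function(jt_t, jt_t1) {
  stopifnot(nrow(jt_t) == 1, nrow(jt_t1) == 1)
  res <- solve_flows(
    pop00 = jt_t$pop00, pop10 = jt_t$pop10, pop01 = jt_t$pop01,
    surv00 = jt_t$surv00, surv10 = jt_t$surv10, surv01 = jt_t$surv01,
    pop00_1 = jt_t1$pop00, pop10_1 = jt_t1$pop10, pop01_1 = jt_t1$pop01)
  structure(c(res, list(pair = attr(jt_t, "pair"), age = jt_t$age)),
            class = "pairwise_flows")
}

# Vectorized flow solver over consecutive ages. All arguments are aligned
# vectors (one element per interval start).
solve_flows <- function(pop00, pop10, pop01, surv00, surv10, surv01,
                        pop00_1, pop10_1, pop01_1, eps = 1e-12) {
  E1 <- surv00 - pop00_1
  E5 <- (surv00 + surv01) - (pop00_1 + pop01_1)  # marginal onsets of i
  E6 <- (surv00 + surv10) - (pop00_1 + pop10_1)  # marginal onsets of j
  E5c <- pmax(E5, 0)
  E6c <- pmax(E6, 0)
  denom <- E5c + E6c
  share <- ifelse(denom > eps, E5c / denom, 0.5)
  a <- ifelse(abs(E1) <= eps & denom <= eps, 0, E1 * share)
  b <- E1 - a
  c_flow <- a - (pop10_1 - surv10)
  d_flow <- b - (pop01_1 - surv01)
  clipped <- sum(a < -eps) + sum(b < -eps) +
    sum(c_flow < -eps) + sum(d_flow < -eps)
  a <- pmax(a, 0); b <- pmax(b, 0)
  c_flow <- pmax(c_flow, 0); d_flow <- pmax(d_flow, 0)
  rate <- function(flow, src) {
    r <- ifelse(src > eps, flow / src, NA_real_)
    ifelse(is.na(r), r, pmin(r, 1))
  }
  list(a = a, b = b, c_flow = c_flow, d_flow = d_flow,
       rate_i_00 = rate(a, pop00), rate_j_00 = rate(b, pop00),
       rate_j_10 = rate(c_flow, pop10), rate_i_01 = rate(d_flow, pop01),
       clipped = clipped,
       missing = sum(pop00 <= eps) * 2 + sum(pop10 <= eps) +
         sum(pop01 <= eps))
}

#' Conditional incidence as a population-weighted average
#'
#' Aggregates pairwise onset rates of a target disease into its
#' conditional incidence for one comorbidity state: the weighted mean of
#' the per-partner rates, each weighted by its pair-cell population.
#' Missing (flagged) pairwise terms are dropped from numerator and
#' denominator.
#'
#' @param rates per-partner onset rates of the target disease from cells
#'   `(0, d_l)`; `NA` marks a missing estimate.
#' @param weights matching pair-cell populations.
#' @return the weighted-average rate, or `NA` if every term is missing.
#' @export
conditional_incidence <- function(rates, weights) {
  stopifnot(length(rates) == length(weights))
  keep <- !is.na(rates) & !is.na(weights)
  if (!any(keep) || sum(weights[keep]) <= 0) return(NA_real_)
  sum(rates[keep] * weights[keep]) / sum(weights[keep])
}

#' Estimate the full incidence surface of a cohort
#'
#' Runs the complete multistate estimation for one sex: builds the
#' `choose(m, 2)` pairwise joint tables along the cohort's age axis,
#' removes mortality, solves the onset flows of every consecutive-age
#' pair, and aggregates the pairwise rates into the conditional one-year
#' incidence of each target disease under each of the `2^(m-1)`
#' comorbidity states without the target.
#'
#' @param cohort a `hypothetical_cohort`.
#' @param mm a `mortality_model`.
#' @param sex stratum.
#' @param diseases diseases to analyze (default all tracked); the cohort
#'   is marginalized to this set first.
#' @param mortality `"state"` (default) computes survivors at full
#'   joint-state resolution -- the additive excess-mortality assumption
#'   applied to each individual's complete disease set -- before
#'   marginalizing into pair cells; `"pair"` uses the literal pair-cell
#'   formula of [apply_mortality()], which ignores out-of-pair excess
#'   deaths.
#' @return a tibble of class `incidence_surface`: `sex`, `age`, `target`,
#'   `state` (bitstring over the ordered analyzed diseases, target bit
#'   0), `incidence`, `flagged`. Attributes: `diseases`, `pairwise` (the
#'   underlying pairwise rate estimates), `report` (clip and missing
#'   counters).
#' @export
build_surface <- function(cohort, mm, sex,
                          diseases = cohort$diseases,
                          mortality = c("state", "pair")) {
  mortality <- match.arg(mortality)
  check_sex(sex)
  m <- length(diseases)
  if (m < 2) stop("need at least 2 diseases", call. = FALSE)
  if (!all(diseases %in% cohort$diseases)) {
    stop("disease not tracked in cohort: ",
         paste(setdiff(diseases, cohort$diseases), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(diseases, cohort$diseases)) {
    cohort <- cohort_marginalize(cohort, diseases)
  } else {
    diseases <- cohort$diseases
  }
  ages <- cohort$ages
  n_step <- length(ages) - 1
  surv_state <- if (mortality == "state") survivors_state(cohort, mm, sex)

  clipped <- 0L
  missing <- 0L
  # pairwise rate arrays: rate[[target]][[partner]] = list(r0, r1, w0, w1)
  rate_tab <- list()
  pw_rows <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      jt <- make_joint_tables(cohort, diseases[i], diseases[j], sex)
      if (mortality == "pair") {
        jt <- apply_mortality(jt, mm)
        sv <- list(c00 = jt$surv00, c10 = jt$surv10, c01 = jt$surv01)
      } else {
        cells <- pair_cells_from_states(surv_state, cohort$states,
                                        match(diseases[i], cohort$diseases),
                                        match(diseases[j], cohort$diseases))
        sv <- cells
      }
      idx <- seq_len(n_step)
      fl <- solve_flows(
        pop00 = jt$pop00[idx], pop10 = jt$pop10[idx], pop01 = jt$pop01[idx],
        surv00 = sv$c00[idx], surv10 = sv$c10[idx], surv01 = sv$c01[idx],
        pop00_1 = jt$pop00[idx + 1], pop10_1 = jt$pop10[idx + 1],
        pop01_1 = jt$pop01[idx + 1])
      clipped <- clipped + fl$clipped
      missing <- missing + fl$missing
      key_ij <- diseases[i]; key_ji <- diseases[j]
      rate_tab[[key_ij]][[key_ji]] <- list(
        r0 = fl$rate_i_00, r1 = fl$rate_i_01,
        w0 = jt$pop00[idx], w1 = jt$pop01[idx])
      rate_tab[[key_ji]][[key_ij]] <- list(
        r0 = fl$rate_j_00, r1 = fl$rate_j_10,
        w0 = jt$pop00[idx], w1 = jt$pop10[idx])
      pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
        sex = sex, age = rep(ages[idx], 4),
        target = rep(c(diseases[i], diseases[j],
                       diseases[j], diseases[i]), each = n_step),
        partner = rep(c(diseases[j], diseases[i],
                        diseases[i], diseases[j]), each = n_step),
        d_partner = rep(c(0L, 0L, 1L, 1L), each = n_step),
        rate = c(fl$rate_i_00, fl$rate_j_00, fl$rate_j_10, fl$rate_i_01),
        pop = c(jt$pop00[idx], jt$pop00[idx], jt$pop10[idx], jt$pop01[idx]))
    }
  }
  pairwise <- dplyr::bind_rows(pw_rows)

  # Aggregate to conditional m-dimensional incidence (weighted average).
  B <- state_matrix(m - 1)          # states over the m-1 partners
  out_rows <- list()
  for (k in seq_len(m)) {
    partners <- diseases[-k]
    r0 <- matrix(NA_real_, n_step, m - 1)
    r1 <- r0; w0 <- r0; w1 <- r0
    for (li in seq_along(partners)) {
      rt <- rate_tab[[diseases[k]]][[partners[li]]]
      r0[, li] <- rt$r0; r1[, li] <- rt$r1
      w0[, li] <- rt$w0; w1[, li] <- rt$w1
    }
    rw0 <- ifelse(is.na(r0), 0, r0 * w0)
    rw1 <- ifelse(is.na(r1), 0, r1 * w1)
    w0m <- ifelse(is.na(r0), 0, w0)
    w1m <- ifelse(is.na(r1), 0, w1)
    num <- rw0 %*% t(1 - B) + rw1 %*% t(B)     # n_step x 2^(m-1)
    den <- w0m %*% t(1 - B) + w1m %*% t(B)
    inc <- ifelse(den > 0, num / den, NA_real_)
    any_missing <- (is.na(r0) %*% t(1 - B) + is.na(r1) %*% t(B)) > 0
    # full-length state bitstrings with the target bit forced to 0
    full_states <- matrix(0L, nrow(B), m)
    full_states[, -k] <- B
    labels <- apply(full_states, 1, state_bitstring)
    out_rows[[k]] <- tibble::tibble(
      sex = sex,
      age = rep(ages[seq_len(n_step)], times = nrow(B)),
      target = diseases[k],
      state = rep(labels, each = n_step),
      incidence = as.vector(inc),
      flagged = as.vector(any_missing) | is.na(as.vector(inc)))
  }
  out <- dplyr::bind_rows(out_rows)
  structure(out, diseases = diseases, pairwise = pairwise,
            report = list(clipped = clipped, missing = missing),
            class = c("incidence_surface", class(tibble::tibble())))
}

# Restrict a cohort to a subset of its diseases by summing states that
# agree on the kept coordinates.
cohort_marginalize <- function(cohort, diseases) {
  keep <- match(diseases, cohort$diseases)
  stopifnot(!anyNA(keep))
  m_new <- length(keep)
  new_state <- as.integer(cohort$states[, keep, drop = FALSE] %*%
                            2^(seq_len(m_new) - 1)) + 1L
  counts <- array(0, dim = c(length(cohort$ages), 2^m_new,
                             length(cohort$sexes)))
  for (si in seq_along(cohort$sexes)) {
    old <- cohort$counts[, , si, drop = FALSE]
    dim(old) <- dim(cohort$counts)[1:2]
    for (s in seq_len(ncol(old))) {
      counts[, new_state[s], si] <- counts[, new_state[s], si] + old[, s]
    }
  }
  hypothetical_cohort(counts, diseases, cohort$ages, cohort$sexes,
                      anchor_age = cohort$anchor_age)
}

#' Write an incidence surface as a long CSV
#'
#' Columns: `sex`, `age`, `target`, `state` (bitstring over the ordered
#' analyzed diseases), `incidence`, `flagged`.
#'
#' @param surface an `incidence_surface`.
#' @param path file path.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
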