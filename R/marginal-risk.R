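#' Age-wise incidence difference between a comorbid and the healthy state
#'
#' Subtracts the target disease's healthy-state incidence from its
#' incidence under the given basic-disease combination, age by age, over
#' the ages where both estimates are unflagged.
#'
#' @param surface an `incidence_surface`.
#' @param k target disease.
#' @param state comorbidity state: bitstring or 0/1 vector over the
#'   surface's ordered disease list; the target's bit must be 0 and at
#'   least one other bit set.
#' @param sex stratum.
#' @return tibble of class `difference_series` with columns `age`,
#'   `diff`; target, state and sex ride along as attributes. Zero rows if
#'   no common unflagged ages exist.
#' @export
difference_series <- function(surface, k, state, sex) {
  diseases <- attr(surface, "diseases")
  m <- length(diseases)
  ki <- match(k, diseases)
  if (is.na(ki)) stop("unknown target disease: ", k, call. = FALSE)
  bits <- as_state_bits(state, m)
  if (bits[ki] != 0) stop("target's own bit must be 0", call. = FALSE)
  if (sum(bits) < 1) stop("state must set at least one basic disease",
                          call. = FALSE)
  healthy <- state_bitstring(rep(0L, m))
  lab <- state_bitstring(bits)
  a <- surface[surface$sex == sex & surface$target == k &
                 surface$state == lab & !surface$flagged, c("age", "incidence")]
  b <- surface[surface$sex == sex & surface$target == k &
                 surface$state == healthy & !surface$flagged,
               c("age", "incidence")]
  joined <- dplyr::inner_join(a, b, by = "age", suffix = c("_state", "_healthy"))
  out <- tibble::tibble(age = joined$age,
                        diff = joined$incidence_state - joined$incidence_healthy)
  out <- out[order(out$age), ]
  structure(out, target = k, state = lab, sex = sex,
            class = c("difference_series", class(tibble::tibble())))
}

#' Summarize a difference series into a marginal risk with a 95% interval
#'
#' The marginal risk is the arithmetic mean of the age-wise differences.
#' The default interval is a t-interval over the age points
#' (`mean +/- t_{0.975, n-1} * sd / sqrt(n)`); a nonparametric bootstrap
#' over ages (percentile interval, seeded) is available as an
#' alternative, since the interval construction behind published
#' comorbidity tables is typically unstated.
#'
#' @param ds a `difference_series`.
#' @param method `"t"` or `"bootstrap"`.
#' @param conf confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap resampling.
#' @return a list: `mean`, `lo`, `hi`, `n`. With one age the interval is
#'   `NA`; with zero ages everything is `NA`.
#' @export
summarize_risk <- function(ds, method = c("t", "bootstrap"), conf = 0.95,
                           n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  x <- ds$diff
  n <- length(x)
  if (n == 0) return(list(mean = NA_real_, lo = NA_real_, hi = NA_real_, n = 0L))
  mu <- mean(x)
  if (n == 1) return(list(mean = mu, lo = NA_real_, hi = NA_real_, n = 1L))
  if (method == "t") {
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) *
      stats::sd(x) / sqrt(n)
    lo <- mu - half; hi <- mu + half
  } else {
    set.seed(seed)
    means <- vapply(seq_len(n_boot),
                    function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                    numeric(1))
    qs <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  }
  list(mean = mu, lo = lo, hi = hi, n = n)
}

#' Trend and autocorrelation diagnostics of a difference series
#'
#' Reports the lag-1 autocorrelation and the linear age trend of the
#' series. The marginal-risk summary treats the series as stationary;
#' these diagnostics are reported, never enforced.
#'
#' @param ds a `difference_series`.
#' @return list with `lag1_acf` and `trend_slope` (per year of age).
#' @export
series_diagnostics <- function(ds) {
  x <- ds$diff
  if (length(x) < 3) return(list(lag1_acf = NA_real_, trend_slope = NA_real_))
  lag1 <- stats::acf(x, lag.max = 1, plot = FALSE,
                     demean = TRUE)$acf[2, 1, 1]
  slope <- unname(stats::coef(stats::lm(x ~ ds$age))[2])
  list(lag1_acf = lag1, trend_slope = slope)
}

#' Marginal-risk table over all targets and basic-disease combinations
#'
#' For every target disease and every comorbidity state with the target
#' absent and at least one basic disease present (`2^m / 2 - 1` states
#' per target), summarizes the age-wise incidence difference versus the
#' healthy state, and ranks states within each (target, number of basic
#' diseases) group by descending mean.
#'
#' @param surface an `incidence_surface`.
#' @param sex stratum.
#' @param method,conf,n_boot,seed passed to [summarize_risk()].
#' @return tibble of class `marginal_risk_table`: `target`, `state`,
#'   `n_basic`, `mean`, `lo`, `hi`, `n_ages`, `rank`.
#' @export
marginal_risk_table <- function(surface, sex, method = "t", conf = 0.95,
                                n_boot = 1000L, seed = 1L) {
  diseases <- attr(surface, "diseases")
  m <- length(diseases)
  S <- state_matrix(m)
  rows <- list()
  for (k in seq_len(m)) {
    states <- which(S[, k] == 0 & rowSums(S) >= 1)
    for (s in states) {
      ds <- difference_series(surface, diseases[k], S[s, ], sex)
      sm <- summarize_risk(ds, method = method, conf = conf,
                           n_boot = n_boot, seed = seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = diseases[k], state = state_bitstring(S[s, ]),
        n_basic = sum(S[s, ]), mean = sm$mean, lo = sm$lo, hi = sm$hi,
        n_ages = sm$n)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::group_by(out, .data$target, .data$n_basic)
  out <- dplyr::mutate(out, rank = rank(-.data$mean, ties.method = "first",
                                        na.last = "keep"))
  out <- dplyr::ungroup(out)
  structure(out, diseases = diseases, sex = sex,
            class = c("marginal_risk_table", class(tibble::tibble())))
}

#' Maximum-impact chain of basic-disease combinations for one target
#'
#' Orders, for a target disease, the basic-disease combinations of sizes
#' 1 to m-1 with the largest marginal risk. In `"nested"` mode (the
#' default, matching the additive column construction of published
#' maximum-impact tables) each step adds to the previous combination the
#' single disease that maximizes the mean difference; in `"exhaustive"`
#' mode each cardinality's argmax is taken independently. Ties break by
#' disease-list order.
#'
#' @param table a `marginal_risk_table`.
#' @param k target disease.
#' @param mode `"nested"` or `"exhaustive"`.
#' @return tibble: `size`, `state`, `added` (nested mode: the disease
#'   added at this step), `mean`, `lo`, `hi`. Truncated (with attribute
#'   `truncated = TRUE`) if summaries are missing at some size.
#' @export
max_impact_chain <- function(table, k, mode = c("nested", "exhaustive")) {
  mode <- match.arg(mode)
  diseases <- attr(table, "diseases")
  m <- length(diseases)
  ki <- match(k, diseases)
  if (is.na(ki)) stop("unknown target disease: ", k, call. = FALSE)
  tk <- table[table$target == k & !is.na(table$mean), ]
  rows <- list()
  current <- rep(0L, m)
  truncated <- FALSE
  for (size in seq_len(m - 1)) {
    if (mode == "exhaustive") {
      cand <- tk[tk$n_basic == size, ]
    } else {
      # states extending `current` by exactly one disease
      cand_bits <- lapply(which(current == 0 & seq_len(m) != ki),
                          function(d) { b <- current; b[d] <- 1L; b })
      labs <- vapply(cand_bits, state_bitstring, character(1))
      cand <- tk[tk$state %in% labs, ]
      cand <- cand[match(labs[labs %in% cand$state], cand$state), ]
    }
    if (nrow(cand) == 0) { truncated <- TRUE; break }
    best <- cand[which.max(cand$mean), ]   # first max: disease-list order
    bits <- as_state_bits(best$state, m)
    added <- if (mode == "nested") {
      diseases[which(bits == 1 & current == 0)]
    } else NA_character_
    rows[[size]] <- tibble::tibble(size = size, state = best$state,
                                   added = added, mean = best$mean,
                                   lo = best$lo, hi = best$hi)
    current <- bits
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truncated") <- truncated
  attr(out, "mode") <- mode
  out
}

#' Mutual-impact pairs across all targets
#'
#' Finds unordered disease pairs `(u, v)` such that `v` is the single
#' basic disease with the greatest marginal risk for target `u` and vice
#' versa -- combinations that promote each other the most.
#'
#' @param table a `marginal_risk_table` covering all targets.
#' @return tibble with columns `disease_a`, `disease_b` (may be empty).
#' @export
mutual_impact_pairs <- function(table) {
  diseases <- attr(table, "diseases")
  m <- length(diseases)
  singles <- table[table$n_basic == 1 & !is.na(table$mean), ]
  best <- stats::setNames(rep(NA_character_, m), diseases)
  for (k in diseases) {
    tk <- singles[singles$target == k, ]
    if (nrow(tk) == 0) next
    bits <- as_state_bits(tk$state[which.max(tk$mean)], m)
    best[k] <- diseases[which(bits == 1)]
  }
  rows <- list()
  for (u in diseases) {
    v <- best[[u]]
    if (is.na(v) || is.na(best[[v]])) next
    if (best[[v]] == u && u < v) {
      rows[[length(rows) + 1]] <- tibble::tibble(disease_a = u, disease_b = v)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(disease_a = character(), disease_b = character()))
  }
  dplyr::bind_rows(rows)
}

#' Write a marginal-risk table as a percentage-formatted CSV
#'
#' Marginal risks and interval bounds are rendered as percentages with
#' two decimals, the convention of published comorbidity-risk tables.
#'
#' @param table a `marginal_risk_table`.
#' @param path file path.
#' @export
write_risk_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$mean_pct <- round_half_up(100 * df$mean, 2)
  df$ci_lo_pct <- round_half_up(100 * df$lo, 2)
  df$ci_hi_pct <- round_half_up(100 * df$hi, 2)
  df <- df[, c("target", "n_basic", "state", "mean_pct", "ci_lo_pct",
               "ci_hi_pct", "rank")]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
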