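#' Hypothetical-cohort container
#'
#' Real-valued population counts indexed by age, joint disease state and
#' sex. States are encoded little-endian over the tracked disease list
#' (state 1 = fully healthy). Constructed by [build_cohort()] or
#' [simulate_oracle_cohort()].
#'
#' @param counts numeric array `length(ages) x 2^m x length(sexes)`.
#' @param diseases tracked disease labels (length m).
#' @param ages integer age axis.
#' @param sexes sex strata labels.
#' @param anchor_age the cohort's anchor age (scaling rate 1 there).
#' @return an object of class `hypothetical_cohort`.
#' @export
hypothetical_cohort <- function(counts, diseases, ages,
                                sexes = c("male", "female"),
                                anchor_age = min(ages)) {
  m <- length(diseases)
  counts <- array(counts, dim = c(length(ages), 2^m, length(sexes)))
  if (any(counts < -1e-9)) {
    stop("cohort counts must be non-negative", call. = FALSE)
  }
  counts[counts < 0] <- 0
  S <- state_matrix(m)
  dimnames(counts) <- list(ages, apply(S, 1, state_bitstring), sexes)
  structure(list(counts = counts, diseases = diseases, ages = as.integer(ages),
                 sexes = sexes, anchor_age = anchor_age,
                 states = S),
            class = "hypothetical_cohort")
}

#' @export
print.hypothetical_cohort <- function(x, ...) {
  cat(sprintf("<hypothetical_cohort: %d diseases, ages %d-%d, sexes %s>\n",
              length(x$diseases), min(x$ages), max(x$ages),
              paste(x$sexes, collapse = "/")))
  invisible(x)
}

#' @export
as_tibble.hypothetical_cohort <- function(x, ...) {
  grid <- expand.grid(age = x$ages, state = seq_len(nrow(x$states)),
                      sex = x$sexes, stringsAsFactors = FALSE)
  out <- tibble::tibble(age = grid$age, sex = grid$sex)
  for (d in seq_along(x$diseases)) {
    out[[x$diseases[d]]] <- x$states[grid$state, d]
  }
  out$count <- as.vector(x$counts)
  out
}

#' Observed survivor counts per age and sex
#'
#' Tabulates the surveyed population by single year of age and sex -- the
#' `p_i(t)` series the hypothetical-cohort construction starts from.
#'
#' @param survey a `survey_dataset`.
#' @param anchor_age age whose population anchors the cohort (scaling 1).
#' @return tibble of class `population_series` with columns `age`, `sex`,
#'   `observed`; [back_cast()] adds the `scaling` column.
#' @export
population_series <- function(survey, anchor_age = min(survey$age)) {
  tab <- as.data.frame(table(age = survey$age, sex = survey$sex),
                       stringsAsFactors = FALSE)
  out <- tibble::tibble(age = as.integer(tab$age), sex = tab$sex,
                        observed = as.numeric(tab$Freq))
  out <- out[order(out$sex, out$age), ]
  structure(out, anchor_age = as.integer(anchor_age),
            class = c("population_series", class(tibble::tibble())))
}

#' Back-cast observed age groups to the anchor age
#'
#' Each observed age group `a > anchor` is traced back year by year with
#' the survey-year mortality rates: the implied anchor-age ancestor count
#' is `p_a / prod_{j=0..a-anchor-1} (1 - s_{anchor+j})`. The scaling rate
#' is `w_a = p_anchor / ancestor_a`, with `w_anchor = 1`, so that after
#' scaling the data behave as a single cohort whose anchor-age population
#' is the observed one.
#'
#' @param pop a `population_series`.
#' @param lt a `life_table` covering every age on the back-cast path.
#' @param sex sexes to process (default both).
#' @return the `population_series` with columns `ancestor` and `scaling`
#'   filled for the requested sexes.
#' @export
back_cast <- function(pop, lt, sex = c("male", "female")) {
  check_sex(sex)
  anchor <- attr(pop, "anchor_age")
  if (!"scaling" %in% names(pop)) pop$scaling <- NA_real_
  if (!"ancestor" %in% names(pop)) pop$ancestor <- NA_real_
  for (s in sex) {
    rows <- which(pop$sex == s & pop$age >= anchor)
    rows <- rows[order(pop$age[rows])]
    ages <- pop$age[rows]
    if (!anchor %in% ages) {
      stop("population series has no anchor-age entry for sex ", s,
           call. = FALSE)
    }
    path_ages <- seq(anchor, max(ages) - 1L)
    srates <- if (length(path_ages)) lifetable_rate(lt, path_ages, s) else numeric(0)
    if (any(srates >= 1)) {
      bad <- path_ages[srates >= 1][1]
      stop("mortality rate is 1 at age ", bad,
           "; back-cast divides by zero", call. = FALSE)
    }
    # cumulative survival from the anchor age up to (age - 1)
    csurv <- c(1, cumprod(1 - srates))
    names(csurv) <- seq(anchor, max(ages))
    p_anchor <- pop$observed[rows[ages == anchor]]
    ancestor <- pop$observed[rows] / csurv[as.character(ages)]
    w <- p_anchor / ancestor
    w[ages == anchor] <- 1
    pop$ancestor[rows] <- ancestor
    pop$scaling[rows] <- w
  }
  pop
}

#' Forward-project a back-cast population series
#'
#' Inverse of [back_cast()]: rebuilds the observed survivor counts from
#' the anchor-age ancestors and the life table. Used to validate the
#' cohort construction (round-trip identity).
#'
#' @param pop a back-cast `population_series`.
#' @param lt the same `life_table`.
#' @return tibble with columns `age`, `sex`, `projected`.
#' @export
forward_project <- function(pop, lt) {
  anchor <- attr(pop, "anchor_age")
  keep <- !is.na(pop$ancestor)
  out <- tibble::tibble(age = pop$age[keep], sex = pop$sex[keep],
                        ancestor = pop$ancestor[keep])
  out$projected <- NA_real_
  for (s in unique(out$sex)) {
    rows <- which(out$sex == s)
    ages <- out$age[rows]
    path_ages <- seq(anchor, max(ages) - 1L)
    srates <- if (length(path_ages)) lifetable_rate(lt, path_ages, s) else numeric(0)
    csurv <- c(1, cumprod(1 - srates))
    names(csurv) <- seq(anchor, max(ages))
    out$projected[rows] <- out$ancestor[rows] * csurv[as.character(ages)]
  }
  out$ancestor <- NULL
  out
}

#' Build the hypothetical cohort from a survey and scaling rates
#'
#' Cross-tabulates the survey per (age, sex) into joint disease-state
#' counts over the tracked diseases, then multiplies every state count of
#' an age group by that group's scaling rate, leaving within-age state
#' proportions unchanged. Ages with no respondents yield a zero row and a
#' warning (downstream estimation flags them as missing).
#'
#' @param survey a `survey_dataset`.
#' @param pop a back-cast `population_series` (with `scaling` filled).
#' @param diseases tracked diseases, a subset of the survey's columns.
#' @param smooth if `TRUE`, a 3-point moving average over age is applied
#'   to every state series after scaling (off by default).
#' @return a [hypothetical_cohort()].
#' @export
build_cohort <- function(survey, pop, diseases = survey_diseases(survey),
                         smooth = FALSE) {
  stopifnot(all(diseases %in% names(survey)))
  if (!"scaling" %in% names(pop) || all(is.na(pop$scaling))) {
    stop("population series has no scaling rates; run back_cast() first",
         call. = FALSE)
  }
  m <- length(diseases)
  sexes <- c("male", "female")
  ages <- seq(min(pop$age), max(pop$age))
  counts <- array(0, dim = c(length(ages), 2^m, length(sexes)))
  X <- as.matrix(as.data.frame(survey)[, diseases, drop = FALSE])
  state <- as.integer(X %*% 2^(seq_len(m) - 1)) + 1L
  empty <- character(0)
  for (si in seq_along(sexes)) {
    in_sex <- survey$sex == sexes[si]
    for (ai in seq_along(ages)) {
      rows <- in_sex & survey$age == ages[ai]
      w_idx <- which(pop$sex == sexes[si] & pop$age == ages[ai])
      w <- if (length(w_idx)) pop$scaling[w_idx] else NA_real_
      if (!any(rows) || is.na(w)) {
        empty <- c(empty, paste0(sexes[si], "/", ages[ai]))
        next
      }
      tab <- tabulate(state[rows], nbins = 2^m)
      counts[ai, , si] <- tab * w
    }
  }
  if (length(empty)) {
    warning("empty age cells left as zero rows: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  if (smooth) {
    for (si in seq_along(sexes)) {
      counts[, , si] <- apply(counts[, , si, drop = FALSE], 2, smooth3)
    }
  }
  hypothetical_cohort(counts, diseases, ages, sexes,
                      anchor_age = attr(pop, "anchor_age"))
}

# 3-point moving average over age, endpoints kept as-is.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

#' Marginal pair-cell populations of a cohort
#'
#' Populations of the four `(d_i, d_j)` cells per age for one sex,
#' marginalized over all other tracked diseases.
#'
#' @keywords internal
cohort_pair_pops <- function(cohort, i, j, sex) {
  di <- match(i, cohort$diseases)
  dj <- match(j, cohort$diseases)
  if (is.na(di) || is.na(dj)) {
    stop("disease not tracked in cohort: ",
         paste(setdiff(c(i, j), cohort$diseases), collapse = ", "),
         call. = FALSE)
  }
  if (di == dj) stop("pair must consist of two distinct diseases", call. = FALSE)
  si <- match(sex, cohort$sexes)
  bi <- cohort$states[, di]
  bj <- cohort$states[, dj]
  cnt <- cohort$counts[, , si, drop = FALSE]
  dim(cnt) <- dim(cohort$counts)[1:2]
  cell <- function(a, b) rowSums(cnt[, bi == a & bj == b, drop = FALSE])
  tibble::tibble(age = cohort$ages,
                 pop00 = cell(0, 0), pop10 = cell(1, 0),
                 pop01 = cell(0, 1), pop11 = cell(1, 1))
}

#' Write / read a cohort as a long-format CSV
#'
#' Columns: `age`, `sex`, one 0/1 column per tracked disease, `count`.
#'
#' @param cohort a `hypothetical_cohort`.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(as_tibble(cohort)), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param anchor_age anchor age to record on the rebuilt cohort.
#' @export
read_cohort_csv <- function(path, anchor_age = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  diseases <- setdiff(names(df), c("age", "sex", "count"))
  ages <- sort(unique(df$age))
  sexes <- unique(df$sex)
  m <- length(diseases)
  counts <- array(0, dim = c(length(ages), 2^m, length(sexes)))
  st <- as.integer(as.matrix(df[, diseases, drop = FALSE]) %*%
                     2^(seq_len(m) - 1)) + 1L
  ai <- match(df$age, ages)
  si <- match(df$sex, sexes)
  counts[cbind(ai, st, si)] <- df$count
  hypothetical_cohort(counts, diseases, ages, sexes,
                      anchor_age = anchor_age %||% min(ages))
}
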