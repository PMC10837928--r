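#' Generate a Gompertz life table
#'
#' One annual death probability per (age, sex):
#' `min(1, a * exp(b * (age - 65)))` with the age offset taken from the
#' lower end of the configured age range, so rates are non-decreasing in
#' age by construction.
#'
#' @param params a [synth_params()] object.
#' @return a tibble of class `life_table` with columns `age`, `sex`,
#'   `mortality`.
#' @export
generate_lifetable <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  ages <- seq(params$age_range[1], params$age_range[2])
  grid <- expand.grid(age = ages, sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  a <- params$gompertz_a[grid$sex]
  b <- params$gompertz_b[grid$sex]
  grid$mortality <- pmin(1, a * exp(b * (grid$age - params$age_range[1])))
  new_lifetable(tibble::as_tibble(grid))
}

new_lifetable <- function(df) {
  stopifnot(all(c("age", "sex", "mortality") %in% names(df)))
  check_prob(df$mortality, "mortality")
  structure(tibble::as_tibble(df),
            class = c("life_table", class(tibble::tibble())))
}

#' Look up annual death probabilities in a life table
#'
#' @param lt a `life_table`.
#' @param age,sex vectors (recycled to common length).
#' @return numeric vector of death probabilities.
#' @export
lifetable_rate <- function(lt, age, sex) {
  key <- paste(age, sex)
  idx <- match(key, paste(lt$age, lt$sex))
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("life table has no entry for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lt$mortality[idx]
}

#' Generate a per-disease excess-mortality table
#'
#' Additive annual death probability attributed to each disease, identical
#' for both sexes, taken from the generator parameters.
#'
#' @param params a [synth_params()] object.
#' @return tibble with columns `disease`, `sex`, `excess_mortality`.
#' @export
generate_excess_mortality <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  grid <- expand.grid(disease = params$disease_names,
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  grid$excess_mortality <- params$excess_mortality[grid$disease]
  tibble::as_tibble(grid)
}

#' Mortality model for the multistate transition estimator
#'
#' Couples the base annual death probability (from the life table) with
#' additive per-disease excess death probabilities: an individual with
#' disease set `D` dies within the year with probability
#' `base(age, sex) + sum over D of excess(d, sex)`.
#'
#' @param lifetable a `life_table`.
#' @param excess a data frame with columns `disease`, `sex`,
#'   `excess_mortality`, or a named per-disease numeric vector applied to
#'   both sexes, or `NULL` for zero excess mortality.
#' @return an object of class `mortality_model`.
#' @export
mortality_model <- function(lifetable, excess = NULL) {
  lt <- new_lifetable(lifetable)
  if (is.null(excess)) {
    excess <- tibble::tibble(disease = character(), sex = character(),
                             excess_mortality = numeric())
  } else if (is.numeric(excess)) {
    stopifnot(!is.null(names(excess)))
    vals <- excess
    excess <- expand.grid(disease = names(vals), sex = c("male", "female"),
                          stringsAsFactors = FALSE)
    excess$excess_mortality <- unname(vals[excess$disease])
  }
  check_prob(excess$excess_mortality, "excess_mortality")
  structure(list(lifetable = lt, excess = tibble::as_tibble(excess)),
            class = "mortality_model")
}

#' Base death probability of a mortality model
#' @param mm a `mortality_model`.
#' @param age,sex vectors.
#' @return numeric vector.
#' @export
alpha_base <- function(mm, age, sex) lifetable_rate(mm$lifetable, age, sex)

#' Excess death probability attributed to one disease
#' @param mm a `mortality_model`.
#' @param disease,sex vectors (recycled).
#' @return numeric vector; 0 for diseases absent from the excess table.
#' @export
alpha_excess <- function(mm, disease, sex) {
  if (nrow(mm$excess) == 0) return(rep(0, max(length(disease), length(sex))))
  n <- max(length(disease), length(sex))
  disease <- rep_len(disease, n)
  sex <- rep_len(sex, n)
  idx <- match(paste(disease, sex), paste(mm$excess$disease, mm$excess$sex))
  out <- mm$excess$excess_mortality[idx]
  out[is.na(out)] <- 0
  out
}

#' Read a life-table or excess-mortality CSV
#'
#' Life-table CSVs have columns `age`, `sex`, `mortality`; excess tables
#' have `disease`, `sex`, `excess_mortality`.
#'
#' @param path file path.
#' @return a `life_table` or a tibble.
#' @export
read_lifetable_csv <- function(path) {
  new_lifetable(utils::read.csv(path, check.names = FALSE,
                                fileEncoding = "UTF-8"))
}

#' @rdname read_lifetable_csv
#' @export
read_excess_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("disease", "sex", "excess_mortality") %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname write_survey_csv
#' @param lt a `life_table`.
#' @export
write_lifetable_csv <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
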