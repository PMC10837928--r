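#' Baseline summary of a survey (counts and percentages)
#'
#' Counts and percentage of the total sample, by sex, by 5-year age band
#' (65-69 ... 100-104, 105+), and per disease. Percentages are of the
#' total N with two decimals, rounded half-up.
#'
#' @param survey a `survey_dataset`.
#' @return tibble with columns `characteristic`, `category`, `n`, `pct`.
#' @export
summarize_survey <- function(survey) {
  n_total <- nrow(survey)
  pct <- function(n) round_half_up(100 * n / n_total, 2)
  rows <- list()
  for (s in c("male", "female")) {
    n <- sum(survey$sex == s)
    rows[[length(rows) + 1]] <- tibble::tibble(
      characteristic = "sex", category = s, n = n, pct = pct(n))
  }
  lo <- 5 * (min(survey$age) %/% 5)
  hi <- max(survey$age)
  band_starts <- seq(lo, hi, by = 5)
  for (b in band_starts) {
    last <- b + 4 >= hi
    in_band <- if (last) survey$age >= b else
      survey$age >= b & survey$age <= b + 4
    label <- if (last) paste0(b, "+") else paste0(b, "-", b + 4)
    rows[[length(rows) + 1]] <- tibble::tibble(
      characteristic = "age", category = label,
      n = sum(in_band), pct = pct(sum(in_band)))
    if (last) break
  }
  for (d in survey_diseases(survey)) {
    n <- sum(survey[[d]] == 1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      characteristic = "disease", category = d, n = n, pct = pct(n))
  }
  dplyr::bind_rows(rows)
}

#' Assemble and validate a pipeline run configuration
#'
#' Either `path` points to a YAML or JSON file, or `...` supplies the
#' fields directly. Exactly one of `inputs` (paths to survey, life-table
#' and optional excess-mortality CSVs) or `synth` (a list of
#' [synth_params()] arguments) must be given.
#'
#' @param path optional config file (`.yaml`/`.yml`/`.json`).
#' @param ... fields overriding / replacing the file contents: `inputs`,
#'   `synth`, `sexes`, `screen` (logical, default `TRUE`), `diseases`
#'   (manual list when `screen` is `FALSE`), `chain_mode`, `ci_method`,
#'   `out_dir`, `seed`, `mortality`.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$sexes <- cfg$sexes %||% c("male", "female")
  check_sex(cfg$sexes)
  cfg$screen <- cfg$screen %||% TRUE
  cfg$chain_mode <- match.arg(cfg$chain_mode %||% "nested",
                              c("nested", "exhaustive"))
  cfg$ci_method <- match.arg(cfg$ci_method %||% "t", c("t", "bootstrap"))
  cfg$mortality <- match.arg(cfg$mortality %||% "state", c("state", "pair"))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% NULL
  has_inputs <- !is.null(cfg$inputs)
  has_synth <- !is.null(cfg$synth)
  if (has_inputs == has_synth) {
    stop("config must provide exactly one of 'inputs' or 'synth'",
         call. = FALSE)
  }
  if (!cfg$screen && is.null(cfg$diseases)) {
    stop("config with screen = FALSE must list 'diseases'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full comorbidity-risk pipeline
#'
#' Executes the stages in order: data generation or ingestion, baseline
#' summary, hypothetical-cohort construction (back-cast and scaling),
#' per-sex network screening, incidence-surface estimation, and
#' marginal-risk analysis (summary table, maximum-impact chains, mutual
#' pairs). Deterministic given the config seed. When `out_dir` is set,
#' every stage writes its CSV there plus a machine-readable
#' `report.json`.
#'
#' @param cfg a [run_config()] (or a path / argument list accepted by it).
#' @return the run report (a list), invisibly including all stage
#'   results under `$results`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, as.list(cfg))
  if (!is.null(cfg$synth)) {
    sp <- do.call(synth_params, c(cfg$synth, list(seed = cfg$seed)))
    survey <- generate_survey(sp)
    lt <- generate_lifetable(sp)
    excess <- generate_excess_mortality(sp)
  } else {
    survey <- read_survey_csv(cfg$inputs$survey)
    lt <- read_lifetable_csv(cfg$inputs$lifetable)
    excess <- if (!is.null(cfg$inputs$excess)) read_excess_csv(cfg$inputs$excess)
  }
  summary_tab <- summarize_survey(survey)
  mm <- mortality_model(lt, excess)
  pop <- back_cast(population_series(survey), lt, sex = cfg$sexes)

  per_sex <- list()
  for (sex in cfg$sexes) {
    net <- build_network(survey, sex)
    stats <- network_zscores(net)
    selected <- if (isTRUE(cfg$screen)) screen_diseases(stats) else
      cfg$diseases
    cohort <- build_cohort(survey, pop, diseases = selected)
    surface <- build_surface(cohort, mm, sex, mortality = cfg$mortality)
    risk <- marginal_risk_table(surface, sex, method = cfg$ci_method,
                                seed = cfg$seed)
    chains <- lapply(stats::setNames(selected, selected), function(k)
      max_impact_chain(risk, k, mode = cfg$chain_mode))
    per_sex[[sex]] <- list(
      network = net, network_stats = stats, selected = selected,
      cohort = cohort, surface = surface, risk = risk, chains = chains,
      mutual_pairs = mutual_impact_pairs(risk),
      report = attr(surface, "report"))
  }

  report <- list(
    seed = cfg$seed,
    n_records = nrow(survey),
    summary = lapply(seq_len(nrow(summary_tab)), function(i)
      as.list(summary_tab[i, ])),
    sexes = lapply(per_sex, function(r) list(
      screened = r$selected,
      state_space = 2^length(r$selected),
      clipped_flows = r$report$clipped,
      missing_estimates = r$report$missing,
      mutual_pairs = if (nrow(r$mutual_pairs)) {
        lapply(seq_len(nrow(r$mutual_pairs)), function(i)
          as.list(r$mutual_pairs[i, ]))
      } else list()))
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(cfg$out_dir, ...)
    utils::write.csv(as.data.frame(summary_tab), p("summary.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    for (sex in names(per_sex)) {
      r <- per_sex[[sex]]
      write_network_csv(r$network, r$network_stats,
                        edge_path = p(paste0("edges_", sex, ".csv")),
                        report_path = p(paste0("network_", sex, ".csv")))
      write_cohort_csv(r$cohort, p(paste0("cohort_", sex, ".csv")))
      write_surface_csv(r$surface, p(paste0("incidence_", sex, ".csv")))
      write_risk_csv(r$risk, p(paste0("risk_", sex, ".csv")))
    }
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  report$results <- per_sex
  invisible(report)
}
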