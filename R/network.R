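#' Build the disease co-occurrence network
#'
#' Traverses every individual in the requested sex stratum; each
#' multimorbid individual contributes 1 to the edge weight of every
#' unordered pair among their diseases, so the weight of pair `(i, j)` is
#' the number of individuals having both. A node's weighted degree is the
#' sum of its incident edge weights. Built from raw survey counts, not
#' scaled cohort counts.
#'
#' @param survey a `survey_dataset`.
#' @param sex `"male"` or `"female"`.
#' @return object of class `comorbidity_network`: disease nodes, the
#'   symmetric weight matrix (zero diagonal), per-node weighted degrees,
#'   the stratum label and its size.
#' @export
build_network <- function(survey, sex) {
  check_sex(sex)
  diseases <- survey_diseases(survey)
  rows <- survey$sex == sex
  if (!any(rows)) stop("survey has no records for sex ", sex, call. = FALSE)
  X <- as.matrix(as.data.frame(survey)[rows, diseases, drop = FALSE])
  W <- crossprod(X)
  diag(W) <- 0
  structure(list(nodes = diseases, weights = W,
                 degree = stats::setNames(rowSums(W), diseases),
                 sex = sex, n = sum(rows)),
            class = "comorbidity_network")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat(sprintf("<comorbidity_network: %d diseases, %s stratum, n = %d>\n",
              length(x$nodes), x$sex, x$n))
  invisible(x)
}

#' Weighted-degree z-scores of a comorbidity network
#'
#' Standardizes each node's weighted degree against the mean and the
#' population (divisor-n) standard deviation of all degrees:
#' `z = (x - mu) / s`. Accepts either a `comorbidity_network` or a named
#' numeric vector of weighted degrees (e.g. a published degree table).
#'
#' @param net a `comorbidity_network`, or a named numeric degree vector.
#' @return tibble of class `network_stats` with columns `disease`,
#'   `degree`, `z`, ordered as given; attributes `mu` and `s` hold the
#'   mean and population standard deviation.
#' @export
network_zscores <- function(net) {
  deg <- if (inherits(net, "comorbidity_network")) net$degree else net
  if (length(deg) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (is.null(names(deg))) {
    stop("degree vector must be named by disease", call. = FALSE)
  }
  mu <- mean(deg)
  s <- sqrt(mean((deg - mu)^2))
  if (s == 0) {
    stop("degenerate degree spread: all weighted degrees are equal",
         call. = FALSE)
  }
  out <- tibble::tibble(disease = names(deg), degree = unname(deg),
                        z = unname((deg - mu) / s))
  structure(out, mu = mu, s = s, threshold = "z > 0 (degree above mean)",
            class = c("network_stats", class(tibble::tibble())))
}

#' Screen significantly comorbid diseases
#'
#' Selects the diseases whose weighted degree lies strictly above the
#' mean (`z > 0`), in descending z order -- the mean weighted degree is
#' the significance threshold.
#'
#' @param stats a `network_stats` tibble from [network_zscores()].
#' @return character vector of selected disease labels.
#' @export
screen_diseases <- function(stats) {
  stopifnot(inherits(stats, "network_stats"))
  sel <- stats[stats$z > 0, ]
  sel$disease[order(-sel$z)]
}

#' Write the network's weighted edge list and degree report
#'
#' The edge list CSV has columns `disease_a`, `disease_b`, `weight`
#' (unordered pairs, zero-weight pairs omitted); the report CSV has
#' `disease`, `degree`, `z`, `selected`.
#'
#' @param net a `comorbidity_network`.
#' @param stats its `network_stats`.
#' @param edge_path,report_path output paths (`NULL` to skip either).
#' @export
write_network_csv <- function(net, stats, edge_path = NULL,
                              report_path = NULL) {
  if (!is.null(edge_path)) {
    idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
    edges <- data.frame(disease_a = net$nodes[idx[, 1]],
                        disease_b = net$nodes[idx[, 2]],
                        weight = net$weights[idx])
    utils::write.csv(edges, edge_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  if (!is.null(report_path)) {
    rep_df <- as.data.frame(stats)
    rep_df$selected <- rep_df$z > 0
    utils::write.csv(rep_df, report_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(NULL)
}
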