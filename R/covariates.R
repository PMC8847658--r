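# Relating the six stability metrics to demographic and cognitive
# covariates: Spearman rank correlations per covariate x metric, and the
# coefficient of determination of an OLS fit of a covariate on all six
# metrics.

.merge_summaries <- function(summaries, metadata) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  stopifnot(is.data.frame(summaries), "subject_id" %in% names(summaries))
  merge(as.data.frame(summaries), metadata, by = "subject_id")
}

#' Spearman correlations between covariates and stability metrics
#'
#' One rank correlation per covariate x metric cell, with pairwise deletion
#' of missing covariate values and a significance flag at `alpha`
#' (raw p values; no multiplicity correction beyond the flag).
#'
#' @param summaries [stability_summary()] rows (data frame or list of rows).
#' @param metadata metadata data frame from [read_metadata()].
#' @param covariates character vector of metadata column names (default:
#'   every numeric metadata column).
#' @param alpha significance level for the flag (default 0.01).
#' @return Data frame with columns `covariate`, `metric`, `rho`, `p_value`,
#'   `n`, `significant`.
#' @export
spearman_table <- function(summaries, metadata, covariates = NULL,
                           alpha = 0.01) {
  d <- .merge_summaries(summaries, metadata)
  metrics <- intersect(stability_metric_names(), names(d))
  if (is.null(covariates))
    covariates <- setdiff(names(metadata)[vapply(metadata, is.numeric,
                                                 logical(1L))], metrics)
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(d)) stop("unknown covariate: ", cv)
    if (all(is.na(d[[cv]]))) stop("covariate '", cv, "' is entirely missing")
    for (mt in metrics) {
      ok <- stats::complete.cases(d[[cv]], d[[mt]])
      if (sum(ok) < 3L)
        stop("fewer than 3 paired observations for ", cv, " x ", mt)
      ct <- suppressWarnings(
        stats::cor.test(d[[cv]][ok], d[[mt]][ok], method = "spearman",
                        exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, metric = mt, rho = unname(ct$estimate),
        p_value = ct$p.value, n = sum(ok),
        significant = ct$p.value < alpha)
    }
  }
  do.call(rbind, rows)
}

#' Explanatory power of the six stability metrics for a covariate
#'
#' Coefficient of determination of the ordinary-least-squares fit of a
#' covariate on the six stability metrics plus an intercept, over complete
#' cases.
#'
#' @param summaries [stability_summary()] rows.
#' @param metadata metadata data frame.
#' @param response name of the covariate to regress on the metrics.
#' @return Numeric R^2 in `[0, 1]`, with attributes `n` (complete cases)
#'   and `degenerate` (`TRUE` when the response is constant, where R^2 is 0
#'   by convention, or the design is rank deficient).
#' @export
ols_r2 <- function(summaries, metadata, response) {
  d <- .merge_summaries(summaries, metadata)
  metrics <- intersect(stability_metric_names(), names(d))
  if (!response %in% names(d)) stop("unknown response: ", response)
  d <- d[stats::complete.cases(d[, c(response, metrics)]), , drop = FALSE]
  if (nrow(d) < length(metrics) + 2L)
    stop("need at least ", length(metrics) + 2L, " complete cases, got ",
         nrow(d))
  if (stats::var(d[[response]]) == 0)
    return(structure(0, n = nrow(d), degenerate = TRUE))
  fml <- stats::reformulate(metrics, response = response)
  fit <- stats::lm(fml, data = d)
  degen <- any(is.na(stats::coef(fit)))
  structure(unname(summary(fit)$r.squared), n = nrow(d), degenerate = degen)
}
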