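#' Analysis configuration
#'
#' Bundles the tunable settings of the three-question pipeline. Unknown
#' arguments are rejected (everything is validated up front, before any
#' stage runs).
#'
#' @param alpha significance threshold (default 0.05).
#' @param min_tests minimum tests per article (default 2).
#' @param include_chi2 keep chi-squared records (default `TRUE`).
#' @param rscale JZS Cauchy prior scale (default 0.707).
#' @param prior a [bib_prior()].
#' @param control a [bib_mcmc_control()].
#' @param run_suite also fit the single-predictor models (slow; default
#'   `FALSE`).
#' @param jif_exclusion_threshold when set, Question 3 additionally refits
#'   after excluding studies with JIF above this value.
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(alpha = 0.05, min_tests = 2,
                            include_chi2 = TRUE, rscale = 0.707,
                            prior = bib_prior(),
                            control = bib_mcmc_control(),
                            run_suite = FALSE,
                            jif_exclusion_threshold = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha: must be in (0,1)")
  if (min_tests < 0) stop("min_tests: must be nonnegative")
  if (rscale <= 0) stop("rscale: must be positive")
  structure(as.list(environment()), class = "analysis_config")
}

#' Question 1: do bibliometrics predict statistical reporting accuracy?
#'
#' Runs the reporting-accuracy pipeline on a corpus: classifies every test
#' for consistency, filters articles below the minimum test count, builds
#' the reported-vs-recomputed cross-tabulation with its beta(1,1)
#' two-proportion Bayes factor, compares citation counts of articles with
#' and without decision errors by a two-sample JZS t-test BF (raw and
#' log-transformed), and fits the zero-inflated Poisson error-count model
#' with the total-tests offset.
#'
#' @param tests a stat-report table with `article_id`.
#' @param articles an article table (`article_id`, `jif`, `citations`,
#'   `n_authors`, `year`, `area`).
#' @param config an [analysis_config()].
#' @return a list: `records`, `article_summaries`, `crosstab`,
#'   `proportion_log_bf10`, `citation_bf` (raw/log), `zip_fit`, and
#'   `suite` when requested.
#' @export
run_question1 <- function(tests, articles, config = analysis_config()) {
  if (!nrow(tests)) stop("empty corpus: no test records supplied")
  records <- classify_consistency(tests, alpha = config$alpha)
  records <- filter_corpus(records, min_tests = config$min_tests,
                           include_chi2 = config$include_chi2)
  if (!nrow(records)) stop("no records left after corpus filtering")
  summaries <- summarize_articles(records)
  ct <- cross_tabulate(records, alpha = config$alpha)
  prop_lbf <- two_proportion_bf10(
    ct$n_recomputed_nonsig_reported_sig, ct$n_recomputed_nonsig,
    ct$n_recomputed_sig_reported_nonsig, ct$n_recomputed_sig, log = TRUE)

  rows <- merge(articles, summaries[, c("article_id", "n_tests",
                                        "n_decision_errors",
                                        "has_decision_error")],
                by = "article_id")
  names(rows)[names(rows) == "n_tests.y"] <- "n_tests"
  rows$n_tests.x <- NULL
  rows$n_errors <- rows$n_decision_errors
  rows <- prepare_model_rows(rows, authors_log = FALSE)

  cit_err <- rows$citations[rows$has_decision_error]
  cit_ok <- rows$citations[!rows$has_decision_error]
  citation_bf <- if (length(cit_err) >= 2 && length(cit_ok) >= 2) {
    list(raw = two_sample_jzs_ttest_bf10(cit_err, cit_ok,
                                         rscale = config$rscale),
         log_transformed = two_sample_jzs_ttest_bf10(
           cit_err, cit_ok, rscale = config$rscale, log_transform = TRUE))
  } else {
    message("citation comparison skipped: one error group too small")
    NULL
  }
  zip_fit <- fit_zip_errors(rows, prior = config$prior,
                            control = config$control)
  suite <- if (config$run_suite)
    single_predictor_suite(rows, "errors", prior = config$prior,
                           control = config$control)
  list(records = records, article_summaries = summaries, crosstab = ct,
       proportion_log_bf10 = prop_lbf, citation_bf = citation_bf,
       model_rows = rows, zip_fit = zip_fit, suite = suite)
}

#' Question 2: do bibliometrics predict evidential value?
#'
#' Scores every significant t, one-df F and r test with default JZS Bayes
#' factors under both design assumptions, transforms the between-subjects
#' BF to the probability scale, and fits beta regressions: one on the
#' evidence probabilities, and an exploratory one on recomputed p-values
#' at or below alpha rescaled into the unit interval.
#'
#' @inheritParams run_question1
#' @return a list: `evidence` (per-test table),
#'   `between_within_correlation` (Spearman), `beta_fit`,
#'   `pvalue_beta_fit`, `n_dropped`, and `suite` when requested.
#' @export
run_question2 <- function(tests, articles, config = analysis_config()) {
  if (!nrow(tests)) stop("empty corpus: no test records supplied")
  records <- classify_consistency(tests, alpha = config$alpha)
  records <- filter_corpus(records, min_tests = config$min_tests,
                           include_chi2 = config$include_chi2)
  ev <- score_evidence(records, alpha = config$alpha,
                       rscale = config$rscale)
  if (!nrow(ev)) {
    message("no significant scorable tests; returning empty result")
    return(list(evidence = ev, beta_fit = NULL, pvalue_beta_fit = NULL,
                n_dropped = 0L, suite = NULL,
                between_within_correlation = NA_real_))
  }
  bw_cor <- stats::cor(ev$log_bf10_between, ev$log_bf10_within,
                       method = "spearman")
  usable <- ev[!ev$dropped, , drop = FALSE]
  rows <- merge(usable, articles, by = "article_id")
  rows <- prepare_model_rows(rows, authors_log = FALSE)
  rows$log_df_std <- as.numeric(scale(log(rows$df)))
  preds <- c("log_jif", "log_citations", "authors", "year_std",
             "log_df_std")
  beta_fit <- fit_beta_evidence(rows, predictors = preds,
                                prior = config$prior,
                                control = config$control)
  # exploratory: model the magnitude of significant recomputed p-values
  prow <- records[records$recomputed_p <= config$alpha &
                    records$family %in% c("t", "F", "r", "z", "chi2"), ,
                  drop = FALSE]
  prow <- merge(prow, articles, by = "article_id")
  prow <- prepare_model_rows(prow, authors_log = FALSE)
  prow$p_scaled <- squeeze_unit_interval(prow$recomputed_p / config$alpha)
  pv_fit <- fit_beta_evidence(prow,
                              predictors = c("log_jif", "log_citations",
                                             "authors", "year_std"),
                              response = "p_scaled",
                              prior = config$prior,
                              control = config$control)
  suite <- if (config$run_suite)
    single_predictor_suite(rows, "evidence", prior = config$prior,
                           control = config$control)
  list(evidence = ev, between_within_correlation = bw_cor,
       beta_fit = beta_fit, pvalue_beta_fit = pv_fit,
       n_dropped = sum(ev$dropped), model_rows = rows, suite = suite)
}

#' Question 3: do bibliometrics predict replication success?
#'
#' Fits the multilevel logistic model of replication success on log-JIF,
#' log-citations and log-authors with area and year as grouping factors;
#' optionally the single-predictor variants, a subset model with
#' surprisingness/prestige ratings when those columns are present, and a
#' refit excluding very-high-JIF studies when the config sets a
#' threshold.
#'
#' @param studies replication table (`jif`, `citations`, `n_authors`,
#'   `year`, `area`, `replicated`, optional `surprisingness`/`prestige`).
#' @param config an [analysis_config()].
#' @return a list: `base_rate`, `logistic_fit`, `subset_fit` (or `NULL`),
#'   `jif_excluded_fit` (or `NULL`), and `suite` when requested.
#' @export
run_question3 <- function(studies, config = analysis_config()) {
  if (!nrow(studies)) stop("empty replication table")
  rows <- prepare_model_rows(studies, authors_log = TRUE)
  fit <- fit_logistic_replication(rows, prior = config$prior,
                                  control = config$control)
  subset_fit <- NULL
  if (all(c("surprisingness", "prestige") %in% names(rows))) {
    rows$surprise_std <- as.numeric(scale(rows$surprisingness))
    rows$prestige_std <- as.numeric(scale(rows$prestige))
    subset_fit <- fit_logistic_replication(
      rows, predictors = c("log_citations", "surprise_std",
                           "prestige_std"),
      prior = config$prior, control = config$control)
  } else {
    message("surprisingness/prestige columns absent; subset model skipped")
  }
  jif_fit <- NULL
  if (!is.null(config$jif_exclusion_threshold)) {
    keep <- rows$jif <= config$jif_exclusion_threshold
    jif_fit <- fit_logistic_replication(rows[keep, , drop = FALSE],
                                        prior = config$prior,
                                        control = config$control)
  }
  suite <- if (config$run_suite)
    single_predictor_suite(rows, "replication", prior = config$prior,
                           control = config$control)
  list(base_rate = mean(rows$replicated), logistic_fit = fit,
       subset_fit = subset_fit, jif_excluded_fit = jif_fit,
       model_rows = rows, suite = suite)
}
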