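#' Single-predictor model suite
#'
#' Fits one model per predictor — each predictor entered alone as a fixed
#' effect, with the content-area random intercept retained and, for the
#' error-count model, the total-tests offset — mirroring how bibliometric
#' indicators are consulted one at a time in evaluation settings. Returns
#' the fits plus a compact report table (effect, 95% CI, LOO R-squared,
#' Savage–Dickey BF10, Rhat).
#'
#' @param data model rows (see [prepare_model_rows()]).
#' @param response_kind `"errors"` (zero-inflated Poisson with offset),
#'   `"evidence"` (beta regression) or `"replication"` (multilevel
#'   logistic; year kept as a grouping factor).
#' @param predictors predictors to model separately.
#' @param prior,control passed to the underlying fits.
#' @param compute_loo include the LOO R-squared column (the slowest step;
#'   default `TRUE`).
#' @return list with `fits` (named list of `bibfit`) and `table`
#'   (`data.frame`).
#' @export
single_predictor_suite <- function(data,
                                   response_kind = c("errors", "evidence",
                                                     "replication"),
                                   predictors = NULL,
                                   prior = bib_prior(),
                                   control = bib_mcmc_control(),
                                   compute_loo = TRUE) {
  response_kind <- match.arg(response_kind)
  if (is.null(predictors)) {
    predictors <- switch(response_kind,
      errors = c("log_jif", "log_citations", "authors", "year_std"),
      evidence = c("log_jif", "log_citations", "authors", "year_std",
                   "log_df_std"),
      replication = c("log_jif", "log_citations", "authors"))
  }
  fitter <- switch(response_kind,
    errors = fit_zip_errors,
    evidence = fit_beta_evidence,
    replication = fit_logistic_replication)
  fits <- list()
  rows <- list()
  for (p in predictors) {
    fit <- fitter(data, predictors = p, prior = prior, control = control)
    fits[[p]] <- fit
    cf <- fit$coefficients[fit$coefficients$name == paste0("b_", p), ]
    rows[[p]] <- data.frame(
      model = response_kind, predictor = p,
      effect = cf$posterior_mean, ci_low = cf$ci_low, ci_high = cf$ci_high,
      loo_r2 = if (compute_loo) as.numeric(loo_r2(fit)) else NA_real_,
      bf10 = predictor_bf10(fit, p),
      rhat = cf$rhat,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(fits = fits, table = table)
}
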