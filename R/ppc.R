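#' Posterior predictive checks
#'
#' Simulates replicate datasets from the fitted model and compares
#' observed summary statistics against their posterior predictive
#' distributions. For each statistic the two-sided tail probability
#' `2 * min(P(T_rep >= T_obs), P(T_rep <= T_obs))` is returned; values
#' near 0 flag aspects of the data the model fails to reproduce. For a
#' well-specified model the tail probabilities are roughly uniform.
#'
#' @param fit a `bibfit`.
#' @param statistics named list of functions mapping a response vector to
#'   a scalar; defaults cover mean, variance and (for counts) the zero
#'   fraction.
#' @param nsim number of replicate datasets.
#' @param seed seed for the replicate simulation (defaults to the fit's).
#' @return a `data.frame` with `statistic`, `observed`, `rep_mean`,
#'   `tail_prob`.
#' @export
posterior_predictive_check <- function(fit, statistics = NULL, nsim = 500,
                                       seed = NULL) {
  if (is.null(statistics)) {
    statistics <- list(mean = mean, variance = stats::var)
    if (fit$model_kind == "zip_errors")
      statistics$zero_fraction <- function(y) mean(y == 0)
  }
  if (is.null(seed)) seed <- fit$seed
  yrep <- simulate(fit, nsim = nsim, seed = seed)
  y <- fit$model_data$y
  rows <- lapply(names(statistics), function(nm) {
    f <- statistics[[nm]]
    t_obs <- f(y)
    t_rep <- apply(yrep, 1, f)
    p_hi <- mean(t_rep >= t_obs)
    p_lo <- mean(t_rep <= t_obs)
    data.frame(statistic = nm, observed = t_obs, rep_mean = mean(t_rep),
               tail_prob = min(1, 2 * min(p_hi, p_lo)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
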