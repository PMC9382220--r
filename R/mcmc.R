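#' MCMC control settings
#'
#' Sampler settings shared by all model fits. Defaults are sized for the
#' package's hierarchical GLMs, which mix quickly under JAGS's glm module;
#' simulation studies typically reduce `n_iter` and `n_chains`.
#'
#' @param n_chains number of chains.
#' @param n_adapt adaptation iterations.
#' @param n_burn burn-in iterations discarded after adaptation.
#' @param n_iter retained iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; chain c uses RNG seed `seed + c`, so the same
#'   seed and control reproduce draws exactly.
#' @param check_convergence fail the fit when any reported coefficient has
#'   split-Rhat above `rhat_max` or effective sample size below `ess_min`.
#' @param rhat_max,ess_min convergence gate thresholds.
#' @return a list of class `"bib_mcmc_control"`.
#' @export
bib_mcmc_control <- function(n_chains = 2, n_adapt = 500, n_burn = 500,
                             n_iter = 2500, thin = 1, seed = 1,
                             check_convergence = TRUE,
                             rhat_max = 1.01, ess_min = 400) {
  stopifnot(n_chains >= 1, n_iter >= 10, seed == round(seed))
  structure(list(n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
                 n_iter = n_iter, thin = thin, seed = as.integer(seed),
                 check_convergence = check_convergence,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "bib_mcmc_control")
}

#' Prior settings for the hierarchical models
#'
#' Weakly regularizing defaults: Normal(0, `beta_sd`) on fixed effects
#' (predictors are entered on standardized or log scales, so sd 2.5 is
#' broad), Half-Normal(0, `ranef_sd`) on random-intercept standard
#' deviations and on the beta-regression dispersion scale
#' (`phi = s^-2`, `s ~ HN(0, ranef_sd)`), and Logistic(0, 1) on the
#' zero-inflation intercept (uniform on the probability scale).
#'
#' @param beta_sd prior standard deviation for fixed-effect coefficients.
#' @param ranef_sd half-normal scale for group-level standard deviations.
#' @return a list of class `"bib_prior"`.
#' @export
bib_prior <- function(beta_sd = 2.5, ranef_sd = 1) {
  stopifnot(beta_sd > 0, ranef_sd > 0)
  structure(list(beta_sd = beta_sd, ranef_sd = ranef_sd),
            class = "bib_prior")
}

# Run a JAGS model and return draws as a list: combined matrix plus
# per-chain matrices (for split-Rhat). Seeds each chain explicitly.
run_jags <- function(model_string, data, monitors, control,
                     modules = "glm") {
  for (m in modules) {
    try(rjags::load.module(m, quiet = TRUE), silent = TRUE)
  }
  inits <- lapply(seq_len(control$n_chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = control$seed + c)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = control$n_chains,
                             n.adapt = control$n_adapt, quiet = TRUE)
  if (control$n_burn > 0)
    stats::update(model, n.iter = control$n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = control$n_iter, thin = control$thin,
                              progress.bar = "none")
  chains <- lapply(samp, as.matrix)
  list(draws = do.call(rbind, chains), chains = chains, mcmc = samp)
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so it detects both between-chain disagreement and within-chain
#' trends (and is defined for a single chain).
#'
#' @param chains list of numeric vectors, one per chain (draws of one
#'   parameter).
#' @return the split-Rhat value (1 at perfect mixing).
#' @export
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- floor(n / 2)
    halves[[length(halves) + 1L]] <- ch[seq_len(h)]
    halves[[length(halves) + 1L]] <- ch[(h + 1):(2 * h)]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Diagnostics table for a set of named parameter columns.
mcmc_diagnostics <- function(fitres, params) {
  rhat <- vapply(params, function(p)
    split_rhat(lapply(fitres$chains, function(ch) ch[, p])), numeric(1))
  ess <- vapply(params, function(p)
    sum(vapply(fitres$chains, function(ch)
      as.numeric(coda::effectiveSize(ch[, p])), numeric(1))), numeric(1))
  data.frame(parameter = params, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

check_convergence_gate <- function(diag, control, params) {
  d <- diag[diag$parameter %in% params, , drop = FALSE]
  bad_r <- d$parameter[d$rhat > control$rhat_max]
  bad_e <- d$parameter[d$ess < control$ess_min]
  if (length(bad_r) || length(bad_e)) {
    stop("convergence gate failed: ",
         if (length(bad_r)) paste0("Rhat > ", control$rhat_max, " for ",
                                   paste(bad_r, collapse = ", "), "; "),
         if (length(bad_e)) paste0("ESS < ", control$ess_min, " for ",
                                   paste(bad_e, collapse = ", ")),
         " — increase n_iter or n_chains")
  }
  invisible(TRUE)
}

# Assemble coefficient summaries (posterior mean, 95% CI, Rhat, ESS).
coef_summaries <- function(draws, diag, coef_names) {
  out <- data.frame(
    name = coef_names,
    posterior_mean = vapply(coef_names, function(p) mean(draws[, p]),
                            numeric(1)),
    ci_low = vapply(coef_names, function(p)
      unname(stats::quantile(draws[, p], 0.025)), numeric(1)),
    ci_high = vapply(coef_names, function(p)
      unname(stats::quantile(draws[, p], 0.975)), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$rhat <- diag$rhat[match(coef_names, diag$parameter)]
  out$ess <- diag$ess[match(coef_names, diag$parameter)]
  rownames(out) <- NULL
  out
}

new_bibfit <- function(model_kind, coefficients, draws, chains, data,
                       stan_data, config, diagnostics, notes = character()) {
  structure(list(model_kind = model_kind, coefficients = coefficients,
                 draws = draws, chains = chains, data = data,
                 model_data = stan_data, config = config,
                 diagnostics = diagnostics, notes = notes,
                 seed = config$control$seed),
            class = "bibfit")
}

#' @export
print.bibfit <- function(x, ...) {
  cat("Hierarchical Bayesian fit:", x$model_kind, "\n")
  cat(sprintf("  %d observations, %d retained draws, seed %d\n",
              nrow(x$data), nrow(x$draws), x$seed))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.bibfit <- function(object, ...) {
  out <- list(model_kind = object$model_kind,
              coefficients = object$coefficients,
              diagnostics = object$diagnostics,
              n_obs = nrow(object$data),
              n_draws = nrow(object$draws),
              notes = object$notes)
  class(out) <- "summary.bibfit"
  out
}

#' @export
print.summary.bibfit <- function(x, ...) {
  cat("Model:", x$model_kind, "—", x$n_obs, "observations,",
      x$n_draws, "draws\n\nCoefficients (posterior mean, 95% CI):\n")
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat("\nAll monitored parameters:\n")
  print(format(x$diagnostics, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bibfit <- function(object, ...) {
  stats::setNames(object$coefficients$posterior_mean,
                  object$coefficients$name)
}
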