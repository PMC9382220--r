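# Generalized Pareto fit to sample tails, profile-likelihood method of
# Zhang & Stephens (2009) with the usual weak prior on the shape.
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of_b <- function(b) -mean(log1p(-b * x))
  ks <- vapply(bs, k_of_b, numeric(1))
  L <- n * (log(bs / ks) - ks - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  k <- k_of_b(b)
  sigma <- k / b
  k <- (k * n + 5) / (n + 10)   # shrink shape toward 0.5 at small n
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / (-k)
}

#' Pareto-smoothed importance-sampling weights
#'
#' Stabilizes importance ratios by fitting a generalized Pareto
#' distribution to the largest 20% of the ratios and replacing them with
#' expected order statistics of the fit, then truncating at the raw
#' maximum. The fitted shape parameter `khat` diagnoses reliability
#' (values above 0.7 are untrustworthy).
#'
#' @param log_ratios vector of log importance ratios for one observation.
#' @return list with normalized `weights` (summing to 1) and `khat`.
#' @export
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  khat <- Inf
  if (length(unique(exc)) >= 5 && max(exc) > 0) {
    fitgpd <- gpd_fit(exc[exc > 0])
    khat <- fitgpd$k
    if (is.finite(khat)) {
      pp <- (seq_len(M) - 0.5) / M
      repl <- log(exp(cutoff) + qgpd(pp, fitgpd$k, fitgpd$sigma))
      lw[tail_ids[order(lw[tail_ids])]] <- pmin(repl, 0)
    }
  }
  w <- exp(lw - max(lw))
  list(weights = w / sum(w), khat = khat)
}

#' LOO-adjusted Bayesian R-squared
#'
#' Out-of-sample analogue of R-squared based on leave-one-out predictive
#' residuals: for each observation the LOO-predictive mean is computed by
#' Pareto-smoothed importance sampling (importance ratios
#' `1 / p(y_i | theta_s)`), and
#' \deqn{R^2_{loo} = 1 - \mathrm{Var}(y - \hat y_{loo}) /
#'   \mathrm{Var}(y).}
#' Unlike the in-sample Bayesian R-squared this penalizes overfitting and
#' can be slightly negative for pure noise. When the Pareto diagnostic
#' flags too many observations (`khat > 0.7` for more than `bad_frac` of
#' them) the function falls back to 10-fold cross-validation, refitting
#' the model per fold.
#'
#' @param fit a `bibfit`.
#' @param max_draws cap on posterior draws used (subsampled for speed).
#' @param bad_frac tolerated fraction of high-`khat` observations before
#'   the k-fold fallback engages (default 0.1).
#' @param kfold_k folds for the fallback.
#' @return the LOO R-squared, with attributes `khat` (vector) and
#'   `method` (`"psis"` or `"kfold"`).
#' @export
loo_r2 <- function(fit, max_draws = 2000, bad_frac = 0.1, kfold_k = 10) {
  ll <- fit_loglik(fit)
  mu <- fit_mu(fit)
  S <- nrow(ll)
  if (S > max_draws) {
    idx <- round(seq(1, S, length.out = max_draws))
    ll <- ll[idx, , drop = FALSE]
    mu <- mu[idx, , drop = FALSE]
  }
  y <- fit$model_data$y
  N <- length(y)
  yloo <- numeric(N)
  khat <- numeric(N)
  for (i in seq_len(N)) {
    ps <- psis_smooth(-ll[, i])
    khat[i] <- ps$khat
    yloo[i] <- sum(ps$weights * mu[, i])
  }
  method <- "psis"
  if (mean(!is.finite(khat) | khat > 0.7) > bad_frac) {
    yloo <- kfold_predict(fit, kfold_k)
    method <- "kfold"
  }
  out <- 1 - stats::var(y - yloo) / stats::var(y)
  if (!is.finite(out)) stop("LOO R2 undefined: degenerate response variance")
  attr(out, "khat") <- khat
  attr(out, "method") <- method
  out
}

# k-fold fallback: refit on k-1 folds, predict held-out means from
# posterior-mean parameters of each fold fit.
kfold_predict <- function(fit, k = 10) {
  data <- fit$data
  N <- nrow(data)
  set.seed(fit$seed)
  folds <- sample(rep(seq_len(k), length.out = N))
  yhat <- numeric(N)
  refit <- switch(fit$model_kind,
    zip_errors = fit_zip_errors,
    beta_evidence = fit_beta_evidence,
    logistic_replication = fit_logistic_replication)
  control <- fit$config$control
  control$check_convergence <- FALSE
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    subfit <- refit(train, predictors = fit$config$predictors,
                    prior = fit$config$prior, control = control)
    yhat[folds == f] <- predict_newdata_mean(subfit, data[folds == f, ,
                                                          drop = FALSE])
  }
  yhat
}

# Posterior-mean prediction for new rows (unknown groups get intercept 0).
predict_newdata_mean <- function(fit, newdata) {
  X <- cbind(Intercept = rep(1, nrow(newdata)))
  for (p in fit$config$predictors) X <- cbind(X, newdata[[p]])
  b <- coef(fit)
  eta <- as.numeric(X %*% b)
  u_cols <- grep("^u\\[", colnames(fit$draws), value = TRUE)
  if (length(u_cols) && !is.null(fit$area_levels)) {
    u_mean <- colMeans(fit$draws[, u_cols, drop = FALSE])
    ai <- match(as.character(newdata$area), fit$area_levels)
    eta <- eta + ifelse(is.na(ai), 0, u_mean[ai])
  }
  if (fit$model_kind == "logistic_replication" &&
      !is.null(fit$year_levels)) {
    v_cols <- grep("^v\\[", colnames(fit$draws), value = TRUE)
    v_mean <- colMeans(fit$draws[, v_cols, drop = FALSE])
    yi <- match(as.character(newdata$year), fit$year_levels)
    eta <- eta + ifelse(is.na(yi), 0, v_mean[yi])
  }
  switch(fit$model_kind,
    zip_errors = {
      pi <- stats::plogis(mean(fit$draws[, "gamma"]))
      (1 - pi) * exp(eta + log(newdata$n_tests))
    },
    beta_evidence = stats::plogis(eta),
    logistic_replication = stats::plogis(eta))
}

#' In-sample Bayesian R-squared
#'
#' The variance-decomposition Bayesian R-squared
#' `var(mu) / (var(mu) + var(y - mu))`, averaged over draws. Reported for
#' comparison with [loo_r2()], which penalizes overfitting.
#'
#' @param fit a `bibfit`.
#' @return posterior-mean Bayesian R-squared.
#' @export
bayes_r2 <- function(fit) {
  mu <- fit_mu(fit)
  y <- fit$model_data$y
  vfit <- apply(mu, 1, stats::var)
  vres <- apply(sweep(mu, 2, y, function(m, yy) yy - m), 1, stats::var)
  mean(vfit / (vfit + vres))
}
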