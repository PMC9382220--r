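#' Prepare article-level model rows
#'
#' Derives the modelling scales used throughout: `log_jif = ln(JIF)`,
#' `log_citations = ln(citations + 1)`, standardized publication year
#' `year_std`, and the author term (raw count, or `ln(authors)` when
#' `authors_log = TRUE`, as in the replication analysis). Rows with a
#' missing or nonpositive impact factor are dropped with a message giving
#' the count.
#'
#' @param data a `data.frame` with columns `jif`, `citations`, `n_authors`,
#'   `year`, `area` (plus response columns used downstream).
#' @param authors_log log-transform the author count?
#' @return the data with derived columns appended.
#' @export
prepare_model_rows <- function(data, authors_log = FALSE) {
  need <- c("jif", "citations", "n_authors", "year", "area")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- !is.finite(data$jif) | data$jif <= 0
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with missing/nonpositive JIF")
    data <- data[!bad, , drop = FALSE]
  }
  if (!nrow(data)) stop("no rows left after dropping missing JIFs")
  data$log_jif <- log(data$jif)
  data$log_citations <- log1p(data$citations)
  ysd <- stats::sd(data$year)
  data$year_std <- if (is.na(ysd) || ysd == 0) 0 else
    (data$year - mean(data$year)) / ysd
  data$authors <- if (authors_log) log(data$n_authors) else data$n_authors
  data
}

# Build the fixed-effects design matrix (intercept first) and check for
# degenerate columns. Predictors are centred (not scaled): slopes keep
# their per-unit interpretation while the intercept moves to the
# covariate means, which decorrelates it from the slopes for the sampler.
build_design <- function(data, predictors) {
  for (p in predictors) {
    if (is.null(data[[p]])) stop("predictor not found: ", p)
    if (stats::sd(data[[p]]) == 0)
      stop("predictor '", p, "' is constant across rows; drop it")
  }
  X <- cbind(Intercept = rep(1, nrow(data)))
  for (p in predictors) X <- cbind(X, data[[p]] - mean(data[[p]]))
  colnames(X) <- c("Intercept", predictors)
  X
}

rename_beta <- function(draws, chains, predictors) {
  old <- paste0("beta[", seq_len(length(predictors) + 1L), "]")
  new <- paste0("b_", c("Intercept", predictors))
  ren <- function(m) {
    cn <- colnames(m)
    cn[match(old, cn)] <- new
    colnames(m) <- cn
    m
  }
  list(draws = ren(draws), chains = lapply(chains, ren), names = new)
}

# Zero-inflation is marginalized out (zeros trick) rather than imputed
# through a latent indicator: the discrete augmentation couples the
# inflation probability to the Poisson zeros and mixes an order of
# magnitude more slowly.
.zip_model <- "
model {
  C <- 10000
  for (i in 1:N) {
    eta[i] <- inprod(X[i, ], beta) + log_exposure[i] + u[area[i]]
    log(lambda[i]) <- eta[i]
    ll[i] <- ifelse(y[i] == 0,
                    log(pi + (1 - pi) * exp(-lambda[i])),
                    log(1 - pi) - lambda[i] + y[i] * eta[i] - logfact[i])
    zeros[i] ~ dpois(C - ll[i])
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  sigma_u ~ dnorm(0, pow(ranef_sd, -2)) T(0, )
  tau_u <- pow(sigma_u + 1.0E-6, -2)
  for (k in 1:K) { beta[k] ~ dnorm(0, pow(beta_sd, -2)) }
  gamma ~ dlogis(0, 1)
  pi <- ilogit(gamma)
}"

.beta_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
    logit(mu[i]) <- inprod(X[i, ], beta) + u[area[i]]
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  sigma_u ~ dnorm(0, pow(ranef_sd, -2)) T(0, )
  tau_u <- pow(sigma_u + 1.0E-6, -2)
  for (k in 1:K) { beta[k] ~ dnorm(0, pow(beta_sd, -2)) }
  s_phi ~ dnorm(0, pow(ranef_sd, -2)) T(1.0E-3, )
  phi <- pow(s_phi, -2)
}"

.logistic_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbern(p[i])
    logit(p[i]) <- inprod(X[i, ], beta) + u[area[i]] + v[yeari[i]]
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  for (j in 1:Jy) { v[j] ~ dnorm(0, tau_v) }
  sigma_u ~ dnorm(0, pow(ranef_sd, -2)) T(0, )
  tau_u <- pow(sigma_u + 1.0E-6, -2)
  sigma_v ~ dnorm(0, pow(ranef_sd, -2)) T(0, )
  tau_v <- pow(sigma_v + 1.0E-6, -2)
  for (k in 1:K) { beta[k] ~ dnorm(0, pow(beta_sd, -2)) }
}"

# Sum-to-zero recentering: the likelihood identifies only b0 + mean(u),
# so per draw the random-intercept mean is swept into the intercept. This
# is a reparameterization of the same posterior that removes the slow
# b0 <-> mean(u) random walk from the reported intercept.
sweep_ranef_mean <- function(m, ranef_prefix) {
  cols <- grep(paste0("^", ranef_prefix, "\\["), colnames(m))
  if (!length(cols)) return(m)
  mu <- rowMeans(m[, cols, drop = FALSE])
  m[, cols] <- m[, cols] - mu
  m[, "beta[1]"] <- m[, "beta[1]"] + mu
  m
}

finish_fit <- function(kind, raw, predictors, data, jags_data, prior,
                       control, extra_monitors, notes = character()) {
  for (pref in c("u", "v")) {
    raw$draws <- sweep_ranef_mean(raw$draws, pref)
    raw$chains <- lapply(raw$chains, sweep_ranef_mean, ranef_prefix = pref)
  }
  ren <- rename_beta(raw$draws, raw$chains, predictors)
  params <- c(ren$names, extra_monitors)
  fitres <- list(draws = ren$draws, chains = ren$chains)
  diag <- mcmc_diagnostics(fitres, params)
  if (control$check_convergence)
    check_convergence_gate(diag, control, ren$names)
  coefs <- coef_summaries(ren$draws, diag, ren$names)
  new_bibfit(kind, coefs, ren$draws, ren$chains, data, jags_data,
             list(predictors = predictors, prior = prior, control = control),
             diag, notes)
}

#' Zero-inflated Poisson regression for decision-error counts
#'
#' Models the number of statistical decision errors per article as a
#' mixture of a structural-zero component (probability `pi`, constant on
#' the logit scale) and a Poisson component whose rate is
#' `exp(X beta + ln(exposure) + u_area)`. The log-exposure offset converts
#' counts to error *rates* per reported test, so rescaling exposure units
#' shifts only the intercept. Content area enters as a random intercept.
#' Fixed effects carry Normal(0, `beta_sd`) priors; the area scale a
#' Half-Normal; the zero-inflation intercept a Logistic(0, 1).
#'
#' The fit fails loudly when any fixed-effect coefficient has split-Rhat
#' above the control's gate (default 1.01) or effective sample size below
#' its floor (default 400).
#'
#' @param data model rows from [prepare_model_rows()], with count response
#'   and exposure columns.
#' @param predictors fixed-effect column names (intercept added
#'   automatically).
#' @param response count response column (default `"n_errors"`).
#' @param exposure offset column, total tests per article (default
#'   `"n_tests"`).
#' @param area grouping column (default `"area"`).
#' @param prior a [bib_prior()].
#' @param control a [bib_mcmc_control()].
#' @return a `bibfit` object.
#' @export
fit_zip_errors <- function(data,
                           predictors = c("log_jif", "log_citations",
                                          "authors", "year_std"),
                           response = "n_errors", exposure = "n_tests",
                           area = "area", prior = bib_prior(),
                           control = bib_mcmc_control()) {
  y <- data[[response]]
  expo <- data[[exposure]]
  if (any(y != round(y) | y < 0)) stop("response must be nonnegative counts")
  if (any(expo < 1)) stop("exposure must be >= 1 for every article")
  if (any(y > expo)) stop("response exceeds exposure for some rows")
  af <- factor(data[[area]])
  if (!nlevels(af)) stop("no area levels present")
  X <- build_design(data, predictors)
  jags_data <- list(N = nrow(X), K = ncol(X), J = nlevels(af), X = X,
                    y = as.integer(y), log_exposure = log(expo),
                    area = as.integer(af), beta_sd = prior$beta_sd,
                    ranef_sd = prior$ranef_sd,
                    zeros = rep(0L, nrow(X)), logfact = lfactorial(y))
  raw <- run_jags(.zip_model, jags_data,
                  c("beta", "u", "sigma_u", "gamma"), control)
  fit <- finish_fit("zip_errors", raw, predictors, data, jags_data, prior,
                    control, c("sigma_u", "gamma"))
  fit$area_levels <- levels(af)
  fit
}

#' Beta regression for bounded evidence scores
#'
#' Models a response strictly inside (0, 1) — the probability-scale
#' evidential value `BF10 / (BF10 + 1)`, or recomputed p-values rescaled
#' into the unit interval — with a logit-linked mean
#' `logit(mu) = X beta + u_area` and a constant precision `phi`
#' (parameterized as `phi = s^-2` with a Half-Normal prior on `s`, which
#' is diffuse on large precisions). Responses at exactly 0 or 1 are
#' rejected; apply [squeeze_unit_interval()] first.
#'
#' @inheritParams fit_zip_errors
#' @param response column name of the (0,1) response (default
#'   `"prob_h1"`).
#' @return a `bibfit` object.
#' @export
fit_beta_evidence <- function(data,
                              predictors = c("log_jif", "log_citations",
                                             "authors", "year_std"),
                              response = "prob_h1", area = "area",
                              prior = bib_prior(),
                              control = bib_mcmc_control()) {
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values; ",
                               "exclude dropped records first")
  if (any(y <= 0 | y >= 1))
    stop("beta regression needs responses strictly inside (0,1); ",
         "apply squeeze_unit_interval() for boundary values")
  af <- factor(data[[area]])
  X <- build_design(data, predictors)
  jags_data <- list(N = nrow(X), K = ncol(X), J = nlevels(af), X = X,
                    y = y, area = as.integer(af), beta_sd = prior$beta_sd,
                    ranef_sd = prior$ranef_sd)
  raw <- run_jags(.beta_model, jags_data,
                  c("beta", "u", "sigma_u", "phi"), control)
  fit <- finish_fit("beta_evidence", raw, predictors, data, jags_data,
                    prior, control, c("sigma_u", "phi"))
  fit$area_levels <- levels(af)
  fit
}

#' Multilevel logistic regression for replication success
#'
#' Models a binary replicated/not outcome with a logit link, fixed effects
#' for the bibliometric predictors, and random intercepts for both content
#' area and publication year (year is a grouping factor here, unlike in
#' the error and evidence models where it is a standardized fixed effect).
#' Complete separation is handled by the regularizing priors; when the
#' sampler still produces extreme coefficients a note is recorded rather
#' than an error.
#'
#' @inheritParams fit_zip_errors
#' @param response logical/0-1 column (default `"replicated"`).
#' @param year grouping column for the year random intercept.
#' @return a `bibfit` object.
#' @export
fit_logistic_replication <- function(data,
                                     predictors = c("log_jif",
                                                    "log_citations",
                                                    "authors"),
                                     response = "replicated",
                                     area = "area", year = "year",
                                     prior = bib_prior(),
                                     control = bib_mcmc_control()) {
  y <- as.integer(data[[response]])
  if (any(!y %in% c(0L, 1L))) stop("response must be binary")
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  af <- factor(data[[area]])
  yf <- factor(data[[year]])
  X <- build_design(data, predictors)
  jags_data <- list(N = nrow(X), K = ncol(X), J = nlevels(af),
                    Jy = nlevels(yf), X = X, y = y,
                    area = as.integer(af), yeari = as.integer(yf),
                    beta_sd = prior$beta_sd, ranef_sd = prior$ranef_sd)
  raw <- run_jags(.logistic_model, jags_data,
                  c("beta", "u", "v", "sigma_u", "sigma_v"), control)
  notes <- character()
  bmax <- max(abs(colMeans(raw$draws[, grep("^beta", colnames(raw$draws)),
                                     drop = FALSE])))
  if (bmax > 10)
    notes <- "extreme coefficients: possible separation, regularized by prior"
  fit <- finish_fit("logistic_replication", raw, predictors, data,
                    jags_data, prior, control, c("sigma_u", "sigma_v"),
                    notes)
  fit$area_levels <- levels(af)
  fit$year_levels <- levels(yf)
  fit
}

#' Compress unit-interval data away from the boundaries
#'
#' The standard adjustment `(y * (n - 1) + 0.5) / n` for beta-regression
#' responses that touch 0 or 1 (e.g. recomputed p-values rescaled by
#' 1/alpha).
#'
#' @param y values in `[0, 1]`.
#' @param n sample size used for the compression (defaults to
#'   `length(y)`).
#' @return values strictly inside (0, 1).
#' @export
squeeze_unit_interval <- function(y, n = length(y)) {
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  (y * (n - 1) + 0.5) / n
}

# Per-draw linear predictors and mean responses --------------------------

# eta: S x N matrix of linear predictors for the fit's own data.
fit_eta <- function(fit) {
  X <- fit$model_data$X
  B <- fit$draws[, paste0("b_", colnames(X)), drop = FALSE]
  eta <- B %*% t(X)
  u_cols <- grep("^u\\[", colnames(fit$draws))
  if (length(u_cols)) {
    U <- fit$draws[, u_cols, drop = FALSE]
    eta <- eta + U[, fit$model_data$area, drop = FALSE]
  }
  if (fit$model_kind == "logistic_replication") {
    V <- fit$draws[, grep("^v\\[", colnames(fit$draws)), drop = FALSE]
    eta <- eta + V[, fit$model_data$yeari, drop = FALSE]
  }
  if (fit$model_kind == "zip_errors")
    eta <- sweep(eta, 2, fit$model_data$log_exposure, "+")
  eta
}

# mu: S x N matrix of expected responses.
fit_mu <- function(fit) {
  eta <- fit_eta(fit)
  switch(fit$model_kind,
    zip_errors = {
      pi <- stats::plogis(fit$draws[, "gamma"])
      (1 - pi) * exp(eta)
    },
    beta_evidence = stats::plogis(eta),
    logistic_replication = stats::plogis(eta)
  )
}

# Pointwise log-likelihood: S x N matrix.
fit_loglik <- function(fit) {
  eta <- fit_eta(fit)
  y <- fit$model_data$y
  S <- nrow(eta)
  switch(fit$model_kind,
    zip_errors = {
      pi <- stats::plogis(fit$draws[, "gamma"])
      lam <- exp(eta)
      ll <- matrix(NA_real_, S, length(y))
      for (i in seq_along(y)) {
        if (y[i] == 0) {
          ll[, i] <- log(pi + (1 - pi) * exp(-lam[, i]))
        } else {
          ll[, i] <- log1p(-pi) +
            stats::dpois(y[i], lam[, i], log = TRUE)
        }
      }
      ll
    },
    beta_evidence = {
      mu <- stats::plogis(eta)
      phi <- fit$draws[, "phi"]
      ll <- matrix(NA_real_, S, length(y))
      for (i in seq_along(y))
        ll[, i] <- stats::dbeta(y[i], mu[, i] * phi,
                                (1 - mu[, i]) * phi, log = TRUE)
      ll
    },
    logistic_replication = {
      p <- stats::plogis(eta)
      ll <- matrix(NA_real_, S, length(y))
      for (i in seq_along(y))
        ll[, i] <- stats::dbinom(y[i], 1, p[, i], log = TRUE)
      ll
    }
  )
}

#' Posterior-mean predictions from a fit
#'
#' Expected response for each training row, averaged over posterior draws
#' (zero-inflation, offsets and group intercepts included).
#'
#' @param object a `bibfit`.
#' @param type `"response"` (default) or `"link"` (posterior-mean linear
#'   predictor).
#' @param ... unused.
#' @return numeric vector, one value per row of the training data.
#' @export
predict.bibfit <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (type == "link") colMeans(fit_eta(object)) else colMeans(fit_mu(object))
}

#' Response residuals against posterior-mean predictions
#'
#' @param object a `bibfit`.
#' @param ... unused.
#' @return `y - E[y | posterior]`, one value per training row.
#' @export
residuals.bibfit <- function(object, ...) {
  object$model_data$y - predict(object)
}

#' Simulate replicate datasets from the posterior
#'
#' Draws `nsim` parameter vectors from the posterior and simulates one
#' replicate response vector from each — the machinery behind
#' [posterior_predictive_check()].
#'
#' @param object a `bibfit`.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return an `nsim x N` matrix of simulated responses.
#' @export
simulate.bibfit <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$draws)
  idx <- sample.int(S, nsim, replace = nsim > S)
  eta <- fit_eta(object)[idx, , drop = FALSE]
  N <- ncol(eta)
  out <- matrix(NA_real_, nsim, N)
  for (s in seq_len(nsim)) {
    out[s, ] <- switch(object$model_kind,
      zip_errors = {
        pi <- stats::plogis(object$draws[idx[s], "gamma"])
        z <- stats::rbinom(N, 1, pi)
        ifelse(z == 1, 0, stats::rpois(N, exp(eta[s, ])))
      },
      beta_evidence = {
        phi <- object$draws[idx[s], "phi"]
        mu <- stats::plogis(eta[s, ])
        stats::rbeta(N, mu * phi, (1 - mu) * phi)
      },
      logistic_replication = stats::rbinom(N, 1, stats::plogis(eta[s, ]))
    )
  }
  out
}
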