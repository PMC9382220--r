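# Shared small fixtures: one ZIP fit and one beta fit reused across tests.
zip_fixture <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      corp <- generate_corpus(corpus_config(n_articles = 250, seed = 101))
      rows <- prepare_model_rows(corp$articles)
      fit <<- fit_zip_errors(rows, control = fast_control(11))
    }
    fit
  }
})

test_that("zip fit rejects malformed inputs", {
  corp <- generate_corpus(corpus_config(n_articles = 40, seed = 2))
  rows <- prepare_model_rows(corp$articles)
  bad <- rows; bad$n_errors <- bad$n_errors + 0.5
  expect_error(fit_zip_errors(bad, control = fast_control(1)), "counts")
  bad2 <- rows; bad2$n_errors[1] <- bad2$n_tests[1] + 5
  expect_error(fit_zip_errors(bad2, control = fast_control(1)),
               "exceeds exposure")
  bad3 <- rows; bad3$log_jif <- 1
  expect_error(fit_zip_errors(bad3, control = fast_control(1)), "constant")
})

test_that("the exposure offset scales expected counts proportionally", {
  fit <- zip_fixture()
  mu1 <- predict(fit)
  rows2 <- fit$data
  rows2$n_tests <- rows2$n_tests * 2L
  fit2 <- fit
  fit2$model_data$log_exposure <- log(rows2$n_tests)
  mu2 <- predict(fit2)
  expect_equal(mu2, 2 * mu1, tolerance = 1e-12)
})

test_that("zip posterior recovers the generating error structure", {
  fit <- zip_fixture()
  cf <- fit$coefficients
  jif <- cf[cf$name == "b_log_jif", ]
  # generator: rate coefficient -0.21 on centred log JIF
  expect_gt(jif$ci_high, -0.21 - 1.5)
  expect_lt(jif$ci_low, -0.21 + 1.5)
  expect_true(all(is.finite(fit$draws)))
})

test_that("beta regression rejects boundary responses and stays in (0,1)", {
  corp <- generate_corpus(corpus_config(n_articles = 80, seed = 31))
  ev <- score_evidence(classify_consistency(corp$tests))
  rows <- merge(ev[!ev$dropped, ], corp$articles, by = "article_id")
  rows <- prepare_model_rows(rows)
  bad <- rows; bad$prob_h1[1] <- 1
  expect_error(fit_beta_evidence(bad, predictors = "log_jif",
                                 control = fast_control(1)),
               "strictly inside")
  fit <- fit_beta_evidence(rows, predictors = c("log_jif", "log_citations"),
                           control = fast_control(5))
  mu <- predict(fit)
  expect_true(all(mu > 0 & mu < 1))
})

test_that("squeeze_unit_interval moves boundaries inward only slightly", {
  y <- c(0, 0.5, 1)
  z <- squeeze_unit_interval(y, n = 100)
  expect_true(all(z > 0 & z < 1))
  expect_equal(z[2], 0.5, tolerance = 0.01)
  expect_error(squeeze_unit_interval(c(-0.1, 0.5)), "0, 1")
})

test_that("logistic fit needs both outcome classes and bounded predictions", {
  rep_tab <- generate_replication_table(replication_config(seed = 8))
  rows <- prepare_model_rows(rep_tab$studies, authors_log = TRUE)
  all1 <- rows; all1$replicated <- 1L
  expect_error(fit_logistic_replication(all1, control = fast_control(1)),
               "classes")
  fit <- fit_logistic_replication(rows, control = fast_control(3))
  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  # negative JIF effect generated at -0.822: sign should be recovered
  expect_lt(coef(fit)[["b_log_jif"]], 0)
})

test_that("same seed and control reproduce draws exactly", {
  corp <- generate_corpus(corpus_config(n_articles = 60, seed = 77))
  rows <- prepare_model_rows(corp$articles)
  ctl <- sim_control(99, n_iter = 300)
  f1 <- fit_zip_errors(rows, control = ctl)
  f2 <- fit_zip_errors(rows, control = ctl)
  expect_identical(f1$draws, f2$draws)
})

test_that("Savage-Dickey matches the conjugate normal analytic BF", {
  # y_i ~ N(theta, 1), theta ~ N(0, tau^2): both the posterior and the
  # Savage-Dickey BF are available in closed form
  set.seed(5)
  tau <- 2.5
  n <- 30
  y <- rnorm(n, 0.4)
  s2n <- 1 / (n + 1 / tau^2)
  mun <- s2n * sum(y)
  bf_analytic <- dnorm(0, 0, tau) / dnorm(0, mun, sqrt(s2n))
  # the null sits ~2.2 sd into the posterior tail; the kernel estimate
  # there needs a large sample for its variance to drop below the
  # tolerance being tested
  draws <- matrix(rnorm(2e5, mun, sqrt(s2n)), ncol = 1,
                  dimnames = list(NULL, "b_theta"))
  fake_fit <- structure(list(draws = draws,
                             config = list(prior = bib_prior(beta_sd = tau))),
                        class = "bibfit")
  bf_sd <- predictor_bf10(fake_fit, "theta")
  expect_lt(abs(bf_sd / bf_analytic - 1), 0.10)
})

test_that("Savage-Dickey is 1 when posterior equals prior and large when not", {
  set.seed(6)
  draws <- matrix(rnorm(8000, 0, 2.5), ncol = 1,
                  dimnames = list(NULL, "b_x"))
  fake <- structure(list(draws = draws,
                         config = list(prior = bib_prior(beta_sd = 2.5))),
                    class = "bibfit")
  expect_lt(abs(predictor_bf10(fake, "x") - 1), 0.15)
  far <- matrix(rnorm(8000, 3, 0.1), ncol = 1,
                dimnames = list(NULL, "b_x"))
  fake$draws <- far
  expect_gt(predictor_bf10(fake, "x"), 3)
  expect_error(predictor_bf10(fake, "absent"), "no draws")
})

test_that("LOO R2 is near zero for noise and high for strong signal", {
  set.seed(12)
  n <- 250
  x <- rnorm(n)
  noise <- data.frame(jif = exp(rnorm(n, 0.7, 0.6)), citations = 0,
                      n_authors = 3, year = 2000,
                      area = sample(letters[1:4], n, TRUE),
                      x = x, y = squeeze_unit_interval(runif(n)))
  noise <- prepare_model_rows(noise)
  f0 <- fit_beta_evidence(noise, predictors = "x", response = "y",
                          control = fast_control(21))
  r0 <- loo_r2(f0)
  expect_lte(as.numeric(r0), 0.05)

  strong <- noise
  strong$y <- plogis(2 * x + rnorm(n, 0, 0.1))
  strong$y <- squeeze_unit_interval(pmin(pmax(strong$y, 1e-4), 1 - 1e-4))
  f1 <- fit_beta_evidence(strong, predictors = "x", response = "y",
                          control = fast_control(22))
  r1 <- loo_r2(f1)
  expect_gt(as.numeric(r1), 0.9)
  # LOO penalizes: no higher than the in-sample Bayesian R2 (+ MC slack)
  expect_lte(as.numeric(r1), bayes_r2(f1) + 0.02)
  expect_lte(as.numeric(r1), 1)
})

test_that("posterior predictive checks pass for self-generated data and flag misfit", {
  fit <- zip_fixture()
  ppc <- posterior_predictive_check(fit, nsim = 300)
  expect_true(all(ppc$tail_prob > 0.01))
  # strongly zero-inflated data with a high Poisson rate: removing the
  # inflation component must make the zero-fraction check flag misfit
  corp <- generate_corpus(corpus_config(n_articles = 150, seed = 301,
                                        error_zero_inflation = 0.5,
                                        error_intercept = log(0.15)))
  rows <- prepare_model_rows(corp$articles)
  zfit <- fit_zip_errors(rows, control = fast_control(13))
  expect_gt(posterior_predictive_check(zfit, nsim = 300)[
    3, "tail_prob"], 0.01)
  broken <- zfit
  broken$draws[, "gamma"] <- -15   # zero-inflation probability ~ 0
  ppc_bad <- posterior_predictive_check(broken, nsim = 300)
  zf <- ppc_bad[ppc_bad$statistic == "zero_fraction", ]
  expect_lt(zf$tail_prob, 0.01)
})

test_that("the single-predictor suite emits one calibrated row per predictor", {
  corp <- generate_corpus(corpus_config(n_articles = 150, seed = 55))
  rows <- prepare_model_rows(corp$articles)
  suite <- single_predictor_suite(rows, "errors",
                                  predictors = c("log_jif", "year_std"),
                                  control = fast_control(7))
  expect_equal(nrow(suite$table), 2L)
  expect_equal(suite$table$predictor, c("log_jif", "year_std"))
  expect_true(all(is.finite(suite$table$bf10)))
  expect_true(all(suite$table$ci_low <= suite$table$effect &
                    suite$table$effect <= suite$table$ci_high))
  rows$const <- 1
  expect_error(single_predictor_suite(rows, "errors",
                                      predictors = "const",
                                      control = fast_control(7)),
               "constant")
})

test_that("convergence gate fails loudly on hopelessly short chains", {
  corp <- generate_corpus(corpus_config(n_articles = 150, seed = 70))
  rows <- prepare_model_rows(corp$articles)
  ctl <- bib_mcmc_control(n_chains = 2, n_adapt = 30, n_burn = 0,
                          n_iter = 40, seed = 1)
  expect_error(suppressWarnings(fit_zip_errors(rows, control = ctl)),
               "convergence gate")
})
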