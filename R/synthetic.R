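#' Configuration for a synthetic literature corpus
#'
#' Defines the generative model for a seeded synthetic literature:
#' article-level bibliometrics, per-article test counts, an effect-size
#' mixture producing test statistics, and a covariate-dependent
#' decision-error injection model with excess zeros. Defaults emulate the
#' structure of a large behavioural-science reporting corpus: about 15
#' tests per article, median impact factor around 2, heavily skewed
#' citation counts mildly dependent on impact factor, publication years
#' 1985–2016, fourteen content areas, roughly three quarters of tests
#' significant, and injected decision errors that are overclaims 84% of
#' the time.
#'
#' @param n_articles number of articles.
#' @param tests_mean,tests_size negative-binomial mean and dispersion for
#'   tests per article (shifted so every article has at least one test).
#' @param jif_meanlog,jif_sdlog log-normal parameters for the journal
#'   impact factor.
#' @param cit_intercept,cit_b_jif,cit_b_year,cit_size negative-binomial
#'   regression of citation counts on log-JIF and standardized year
#'   (log link), with dispersion `cit_size`.
#' @param authors_lambda Poisson rate for authors beyond the first.
#' @param year_range inclusive integer interval of publication years.
#' @param area_levels,area_weights content-area labels and mixing weights
#'   (weights are normalized).
#' @param error_zero_inflation probability an article belongs to the
#'   never-errs class.
#' @param error_intercept log per-test decision-error rate at covariate
#'   means.
#' @param error_b_jif,error_b_citations,error_b_year,error_b_authors
#'   log-scale coefficients of the per-test error rate on centred log-JIF,
#'   centred log-citations, standardized year and centred author count.
#' @param null_prop proportion of tests with a true effect size of zero.
#' @param effect_scale Cauchy scale of the alternative effect sizes
#'   (truncated to |effect| < `effect_trunc`).
#' @param effect_trunc truncation bound for effect sizes.
#' @param direction_asymmetry probability an injected decision error is an
#'   overclaim.
#' @param chi2_miscode_prob probability a chi-squared report carries its
#'   sample size miscoded as the degrees of freedom.
#' @param seed integer seed; generation is deterministic given the
#'   config.
#' @return a list of class `"corpus_config"`.
#' @export
corpus_config <- function(n_articles = 1000,
                          tests_mean = 14.8, tests_size = 3,
                          jif_meanlog = 0.7, jif_sdlog = 0.6,
                          cit_intercept = log(30), cit_b_jif = 0.5,
                          cit_b_year = 0.2, cit_size = 0.8,
                          authors_lambda = 2.1,
                          year_range = c(1985, 2016),
                          area_levels = c("clinical", "cognitive",
                                          "counselling", "developmental",
                                          "education", "experimental",
                                          "general", "health",
                                          "industrial", "law",
                                          "methodology", "neuroscience",
                                          "social", "other"),
                          area_weights = NULL,
                          error_zero_inflation = 0.3,
                          error_intercept = log(0.02),
                          error_b_jif = -0.21,
                          error_b_citations = 0,
                          error_b_year = -0.11,
                          error_b_authors = 0,
                          null_prop = 0.2,
                          effect_scale = 0.707,
                          effect_trunc = 2,
                          direction_asymmetry = 0.84,
                          chi2_miscode_prob = 0.05,
                          seed = 1) {
  if (is.null(area_weights))
    area_weights <- rep(1 / length(area_levels), length(area_levels))
  if (length(area_weights) != length(area_levels))
    stop("area_weights: must match area_levels in length")
  if (any(area_weights < 0)) stop("area_weights: must be nonnegative")
  area_weights <- area_weights / sum(area_weights)
  chk01 <- function(x, nm) if (x < 0 || x > 1) stop(nm, ": must lie in [0,1]")
  chk01(error_zero_inflation, "error_zero_inflation")
  chk01(null_prop, "null_prop")
  chk01(direction_asymmetry, "direction_asymmetry")
  chk01(chi2_miscode_prob, "chi2_miscode_prob")
  if (n_articles < 1) stop("n_articles: must be positive")
  if (tests_mean <= 1) stop("tests_mean: must exceed 1")
  structure(as.list(environment()), class = "corpus_config")
}

rtrunc_cauchy <- function(n, scale, trunc) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rcauchy(length(need), 0, scale)
    ok <- abs(x) < trunc
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic literature corpus
#'
#' Draws article metadata, per-test statistics (from the configured
#' null/alternative effect-size mixture and simulated sample sizes),
#' renders every test as APA text, and injects decision errors by
#' rewriting reported p-values across the significance boundary —
#' overclaims become `"p < .05"` reports of truly nonsignificant tests,
#' underclaims `"p > .05"` reports of truly significant ones — leaving
#' the statistic itself untouched. All randomness is governed by the
#' config seed; the same config yields byte-identical output.
#'
#' @param config a [corpus_config()].
#' @return list with `articles` (bibliometric table with error counts),
#'   `tests` (stat-report table), `text` (one APA-rendered pseudo-article
#'   per row of `articles`) and `truth` (generating parameters, per-test
#'   true effects and p-values, per-article injected error counts).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  n <- config$n_articles
  art <- data.frame(
    article_id = sprintf("A%05d", seq_len(n)),
    jif = stats::rlnorm(n, config$jif_meanlog, config$jif_sdlog),
    year = sample(seq(config$year_range[1], config$year_range[2]), n,
                  replace = TRUE),
    n_authors = 1L + stats::rpois(n, config$authors_lambda),
    area = sample(config$area_levels, n, replace = TRUE,
                  prob = config$area_weights),
    stringsAsFactors = FALSE
  )
  year_std <- (art$year - mean(art$year)) /
    max(stats::sd(art$year), 1e-9)
  cit_mu <- exp(config$cit_intercept +
                  config$cit_b_jif * (log(art$jif) - config$jif_meanlog) +
                  config$cit_b_year * year_std)
  art$citations <- stats::rnbinom(n, size = config$cit_size, mu = cit_mu)
  art$n_tests <- 1L + stats::rnbinom(n, size = config$tests_size,
                                     mu = config$tests_mean - 1)

  # per-test true effects and statistics
  total <- sum(art$n_tests)
  aidx <- rep(seq_len(n), art$n_tests)
  fam <- sample(c("t", "F", "r", "chi2", "z"), total, replace = TRUE,
                prob = c(0.45, 0.35, 0.10, 0.08, 0.02))
  is_null <- stats::runif(total) < config$null_prop
  delta <- ifelse(is_null, 0,
                  rtrunc_cauchy(total, config$effect_scale,
                                config$effect_trunc))
  n_total <- pmin(pmax(round(stats::rlnorm(total, log(50), 0.5)), 10), 500)
  tests <- generate_tests(fam, delta, n_total, config)
  tests$article_id <- art$article_id[aidx]

  # decision-error injection (covariate-dependent, zero-inflated)
  lcit_c <- log1p(art$citations) - mean(log1p(art$citations))
  ljif_c <- log(art$jif) - mean(log(art$jif))
  auth_c <- art$n_authors - mean(art$n_authors)
  log_rate <- config$error_intercept + config$error_b_jif * ljif_c +
    config$error_b_citations * lcit_c + config$error_b_year * year_std +
    config$error_b_authors * auth_c
  structural_zero <- stats::runif(n) < config$error_zero_inflation
  target_errors <- ifelse(structural_zero, 0L,
                          stats::rpois(n, exp(log_rate) * art$n_tests))
  injected <- inject_errors(tests, aidx, target_errors,
                            config$direction_asymmetry)
  tests <- injected$tests
  art$n_injected_errors <- injected$per_article
  art$n_errors <- art$n_injected_errors  # alias used by the model fits

  text <- render_articles(tests)
  text <- text[match(art$article_id, names(text))]
  text[is.na(text)] <- ""
  names(text) <- art$article_id

  truth <- list(
    config = config,
    per_test = data.frame(article_id = tests$article_id,
                          delta = delta,
                          true_p = injected$true_p,
                          injected_error = tests$injected_error,
                          stringsAsFactors = FALSE),
    per_article = data.frame(article_id = art$article_id,
                             structural_zero = structural_zero,
                             target_errors = target_errors,
                             injected_errors = injected$per_article,
                             log_rate = log_rate,
                             stringsAsFactors = FALSE),
    error_coefficients = c(intercept = config$error_intercept,
                           log_jif = config$error_b_jif,
                           log_citations = config$error_b_citations,
                           year_std = config$error_b_year,
                           authors = config$error_b_authors),
    zero_inflation = config$error_zero_inflation
  )
  tests$injected_error <- NULL
  class(tests) <- c("stat_report_df", "data.frame")
  list(articles = art, tests = tests, text = text, truth = truth)
}

# Draw family-appropriate statistics for given effect sizes and total
# sample sizes, compute the true p, and format honest reports.
generate_tests <- function(fam, delta, n_total, config) {
  total <- length(fam)
  df1 <- rep(NA_real_, total)
  df2 <- rep(NA_real_, total)
  reported_n <- rep(NA_integer_, total)
  statistic <- numeric(total)
  for (i in seq_len(total)) {
    N <- n_total[i]
    if (fam[i] == "t") {
      df2[i] <- N - 2
      neff <- N / 4
      statistic[i] <- stats::rt(1, df2[i], ncp = delta[i] * sqrt(neff))
    } else if (fam[i] == "F") {
      d1 <- sample(c(1, 1, 1, 2, 3), 1)
      df1[i] <- d1
      df2[i] <- N - d1 - 1
      neff <- N / 4
      statistic[i] <- stats::rf(1, d1, df2[i], ncp = delta[i]^2 * neff)
    } else if (fam[i] == "r") {
      df2[i] <- N - 2
      neff <- N
      tval <- stats::rt(1, df2[i], ncp = delta[i] * sqrt(neff))
      statistic[i] <- tval / sqrt(tval^2 + df2[i])
    } else if (fam[i] == "chi2") {
      d <- sample(1:4, 1)
      miscoded <- stats::runif(1) < config$chi2_miscode_prob
      reported_n[i] <- N
      df2[i] <- if (miscoded) N else d
      statistic[i] <- stats::rchisq(1, d, ncp = delta[i]^2 * N / 4)
    } else {
      statistic[i] <- stats::rnorm(1, delta[i] * sqrt(N / 4))
    }
  }
  statistic <- round(statistic, 2)
  statistic[fam == "r" & abs(statistic) >= 1] <-
    0.99 * sign(statistic[fam == "r" & abs(statistic) >= 1])
  out <- data.frame(
    article_id = NA_character_, family = fam, df1 = df1, df2 = df2,
    reported_n = reported_n, statistic = statistic,
    p_comparator = "eq", reported_p = NA_real_, p_decimals = 2L,
    one_tailed = FALSE, source_start = NA_integer_,
    source_end = NA_integer_, stringsAsFactors = FALSE
  )
  true_p <- vapply(seq_len(total), function(i)
    recompute_p_one(out$family[i], out$df1[i], out$df2[i],
                    out$statistic[i], "two"), numeric(1))
  # honest reporting: exact-p style, "< .001" for tiny p
  p_dec <- sample(c(2L, 3L), total, replace = TRUE, prob = c(0.7, 0.3))
  out$p_decimals <- p_dec
  out$reported_p <- round(true_p, p_dec)
  tiny <- true_p < 0.001
  out$p_comparator[tiny] <- "lt"
  out$reported_p[tiny] <- 0.001
  out$p_decimals[tiny] <- 3L
  attr(out, "true_p") <- true_p
  out
}

# Rewrite reported p across the alpha boundary for randomly chosen tests.
inject_errors <- function(tests, aidx, target_errors, p_over,
                          alpha = 0.05) {
  true_p <- attr(tests, "true_p")
  tests$injected_error <- "none"
  per_article <- integer(length(target_errors))
  for (a in which(target_errors > 0)) {
    rows <- which(aidx == a)
    nonsig <- rows[true_p[rows] > alpha &
                     tests$injected_error[rows] == "none"]
    sig <- rows[true_p[rows] <= alpha &
                  tests$injected_error[rows] == "none"]
    for (e in seq_len(target_errors[a])) {
      over <- stats::runif(1) < p_over
      if (over && length(nonsig) == 0 && length(sig) > 0) over <- FALSE
      if (!over && length(sig) == 0 && length(nonsig) > 0) over <- TRUE
      if (over && length(nonsig) > 0) {
        i <- nonsig[1]
        nonsig <- nonsig[-1]
        tests$p_comparator[i] <- "lt"
        tests$reported_p[i] <- alpha
        tests$p_decimals[i] <- 2L
        tests$injected_error[i] <- "overclaim"
        per_article[a] <- per_article[a] + 1L
      } else if (!over && length(sig) > 0) {
        i <- sig[1]
        sig <- sig[-1]
        tests$p_comparator[i] <- "gt"
        tests$reported_p[i] <- alpha
        tests$p_decimals[i] <- 2L
        tests$injected_error[i] <- "underclaim"
        per_article[a] <- per_article[a] + 1L
      }
    }
  }
  list(tests = tests, per_article = per_article, true_p = true_p)
}

render_articles <- function(tests) {
  parts <- split(seq_len(nrow(tests)), tests$article_id)
  vapply(parts, function(rows) {
    rendered <- render_stat_report(tests[rows, , drop = FALSE])
    paste0("The analysis showed ", rendered, ".", collapse = " ")
  }, character(1))
}

#' Configuration for a synthetic replication-outcome table
#'
#' Emulates a replication-project collation: by default 190 original
#' studies drawn from 27 journals across 7 content areas, with a logistic
#' model for replication success whose defaults echo the structure such
#' collations show — a base success rate of 42.1% and a negative
#' association with the journal impact factor.
#'
#' @param n_studies number of original studies.
#' @param n_journals number of distinct journals.
#' @param area_levels content-area labels (7 by default).
#' @param base_rate marginal replication success rate; the generator
#'   calibrates its intercept against the simulated covariate spread so
#'   the expected success fraction equals this value.
#' @param b_jif,b_citations,b_authors logistic coefficients on centred
#'   log-JIF, centred log-citations(+1) and centred log-authors.
#' @param b_surprise,b_prestige effects of the optional surprisingness and
#'   prestige ratings; set `include_ratings = FALSE` to omit the columns.
#' @param include_ratings emit surprisingness/prestige columns?
#' @param jif_meanlog,jif_sdlog journal impact-factor distribution.
#' @param year_range publication-year interval.
#' @param seed integer seed.
#' @return a list of class `"replication_config"`.
#' @export
replication_config <- function(n_studies = 190, n_journals = 27,
                               area_levels = c("clinical", "cognitive",
                                               "social", "jdm", "general",
                                               "marketing", "other"),
                               base_rate = 0.421,
                               b_jif = -0.822, b_citations = 0.237,
                               b_authors = 0.179,
                               b_surprise = -0.663, b_prestige = 0,
                               include_ratings = TRUE,
                               jif_meanlog = log(3), jif_sdlog = 0.8,
                               year_range = c(1990, 2014), seed = 1) {
  if (base_rate <= 0 || base_rate >= 1) stop("base_rate: must be in (0,1)")
  if (n_studies < 10) stop("n_studies: too few")
  structure(as.list(environment()), class = "replication_config")
}

#' Generate a synthetic replication-outcome table
#'
#' Draws journals with log-normal impact factors, assigns studies to
#' journals and areas, and simulates binary replication outcomes from the
#' configured logistic model (predictors centred; the intercept is
#' calibrated so the marginal success rate equals `base_rate`).
#'
#' @param config a [replication_config()].
#' @return list with `studies` (one row per original study: `jif`,
#'   `citations`, `n_authors`, `year`, `area`, `replicated`, optional
#'   `surprisingness`/`prestige`) and `truth` (generating coefficients).
#' @export
generate_replication_table <- function(config) {
  stopifnot(inherits(config, "replication_config"))
  set.seed(config$seed)
  n <- config$n_studies
  journal_jif <- stats::rlnorm(config$n_journals, config$jif_meanlog,
                               config$jif_sdlog)
  jidx <- sample(config$n_journals, n, replace = TRUE)
  studies <- data.frame(
    study_id = sprintf("S%03d", seq_len(n)),
    journal = sprintf("J%02d", jidx),
    jif = journal_jif[jidx],
    citations = stats::rnbinom(n, size = 1, mu = 60),
    n_authors = 1L + stats::rpois(n, 2.5),
    year = sample(seq(config$year_range[1], config$year_range[2]), n,
                  replace = TRUE),
    area = sample(config$area_levels, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  lj <- log(studies$jif) - mean(log(studies$jif))
  lc <- log1p(studies$citations) - mean(log1p(studies$citations))
  la <- log(studies$n_authors) - mean(log(studies$n_authors))
  spread <- config$b_jif * lj + config$b_citations * lc +
    config$b_authors * la
  if (config$include_ratings) {
    studies$surprisingness <- round(stats::runif(n, 1, 7), 1)
    studies$prestige <- round(stats::runif(n, 1, 7), 1)
    spread <- spread +
      config$b_surprise * (studies$surprisingness -
                             mean(studies$surprisingness)) +
      config$b_prestige * (studies$prestige - mean(studies$prestige))
  }
  # base_rate is the marginal success rate (the quantity a collation
  # reports): calibrate the intercept against the covariate spread, so
  # that mean(plogis(eta)) = base_rate
  b0 <- stats::uniroot(function(b)
    mean(stats::plogis(b + spread)) - config$base_rate,
    interval = c(-20, 20), tol = 1e-10)$root
  eta <- b0 + spread
  studies$replicated <- stats::rbinom(n, 1, stats::plogis(eta))
  truth <- list(config = config,
                coefficients = c(intercept = b0,
                                 log_jif = config$b_jif,
                                 log_citations = config$b_citations,
                                 log_authors = config$b_authors),
                linear_predictor = eta)
  list(studies = studies, truth = truth)
}
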