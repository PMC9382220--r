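# Independent oracles used across the test files.

# JZS Bayes factor by quadrature over the auxiliary variance g, using the
# inverse-gamma mixture representation of the Cauchy prior. This route
# never touches the noncentral t density the package integrates, so it is
# an independent check of the same integral.
jzs_g_oracle <- function(t, nu, neff, r = 0.707) {
  logint <- function(x) {  # x = log g
    g <- exp(x)
    -0.5 * log1p(neff * g) -
      ((nu + 1) / 2) * log1p(t^2 / ((1 + neff * g) * nu)) +
      log(r) - 0.5 * log(2 * pi) - 1.5 * x - r^2 / (2 * g) + x
  }
  xs <- seq(-30, 30, length.out = 4001)
  m <- max(logint(xs))
  f <- function(x) exp(logint(x) - m)
  I <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
  lognum <- m + log(I)
  logden <- -((nu + 1) / 2) * log1p(t^2 / nu)
  lognum - logden   # log BF10
}

# Tail probability by direct numerical integration of the reference
# density (independent of the p* distribution functions the package
# calls).
integrate_tail_p <- function(family, df1, df2, statistic,
                             tails = "two") {
  dens <- switch(family,
    t = function(x) stats::dt(x, df2),
    z = function(x) stats::dnorm(x),
    F = function(x) stats::df(x, df1, df2),
    chi2 = function(x) stats::dchisq(x, df2))
  if (family %in% c("t", "z")) {
    p1 <- stats::integrate(dens, abs(statistic), Inf,
                           rel.tol = 1e-12)$value
    if (tails == "two") 2 * p1 else p1
  } else {
    # integrate the body, not the tail: stable when the statistic sits
    # far left of the distribution's mass
    1 - stats::integrate(dens, 0, statistic, rel.tol = 1e-12)$value
  }
}

# Short-chain control for simulation studies: coverage is read off the
# credible intervals, so the convergence gate is relaxed and a single
# chain suffices.
sim_control <- function(seed, n_iter = 600) {
  bib_mcmc_control(n_chains = 1, n_adapt = 200, n_burn = 200,
                   n_iter = n_iter, seed = seed,
                   check_convergence = FALSE)
}

# Moderate control for end-to-end harness tests.
fast_control <- function(seed) {
  bib_mcmc_control(n_chains = 2, n_adapt = 300, n_burn = 300,
                   n_iter = 800, seed = seed, check_convergence = FALSE)
}

# Random valid stat reports for round-trip properties.
random_stat_reports <- function(n, seed = 1) {
  set.seed(seed)
  fam <- sample(c("t", "F", "r", "chi2", "z"), n, replace = TRUE)
  df1 <- ifelse(fam == "F", sample(1:5, n, replace = TRUE), NA_real_)
  df2 <- ifelse(fam == "z", NA_real_, sample(2:500, n, replace = TRUE))
  rep_n <- ifelse(fam == "chi2" & stats::runif(n) < 0.5,
                  sample(20:2000, n, replace = TRUE), NA_integer_)
  statistic <- round(ifelse(fam == "r", stats::runif(n, -0.99, 0.99),
                     ifelse(fam %in% c("F", "chi2"),
                            stats::rchisq(n, 3),
                            stats::rnorm(n, 0, 2))), 2)
  cmp <- sample(c("eq", "lt", "gt", "ns"), n, replace = TRUE,
                prob = c(0.6, 0.25, 0.05, 0.1))
  dec <- sample(2:3, n, replace = TRUE)
  p <- ifelse(cmp == "ns", NA_real_,
              round(stats::runif(n, 0.001, 0.999), dec))
  one_t <- stats::runif(n) < 0.1
  stat_report(family = fam, df1 = df1, df2 = df2, reported_n = rep_n,
              statistic = statistic, p_comparator = cmp, reported_p = p,
              p_decimals = dec, one_tailed = one_t,
              article_id = sprintf("A%04d", seq_len(n)))
}
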