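#' Convert a one-df F statistic to t
#'
#' For a one-numerator-df F test, `t = sqrt(F)` (the sign of the underlying
#' contrast is unavailable from an F report; the JZS Bayes factor depends
#' on t only through its magnitude under the symmetric Cauchy prior).
#'
#' @param f_value nonnegative F statistic(s).
#' @param df1 numerator degrees of freedom; must equal 1.
#' @return `sqrt(f_value)`.
#' @export
f_to_t <- function(f_value, df1 = 1) {
  if (any(df1 != 1))
    stop("only one-numerator-df F tests can be converted to t (df1 = 1)")
  if (any(f_value < 0)) stop("F statistics are nonnegative")
  sqrt(f_value)
}

#' Convert a Pearson correlation to t
#'
#' `t = r * sqrt(df / (1 - r^2))`, the exact test statistic for a
#' correlation with `df = n - 2` degrees of freedom. Sign is preserved.
#'
#' @param r_value correlation(s), strictly inside (-1, 1).
#' @param df degrees of freedom (> 0).
#' @return t statistic(s).
#' @export
r_to_t <- function(r_value, df) {
  if (any(abs(r_value) >= 1)) stop("|r| must be < 1")
  if (any(df <= 0)) stop("df must be positive")
  r_value * sqrt(df / (1 - r_value^2))
}

#' Estimate sample size from degrees of freedom
#'
#' When only a t statistic and its degrees of freedom are reported, sample
#' size is recovered as `N = df + 1` for a one-sample (within-subjects)
#' design and `N1 = N2 = (df + 2) / 2` for a two-sample (between-subjects)
#' design, rounded to the nearest integer with ties rounded away from
#' zero; each group size is floored at 2.
#'
#' @param df degrees of freedom (>= 1).
#' @param design `"one_sample"` or `"two_sample"`.
#' @return for `"one_sample"`, a vector of N; for `"two_sample"`, a
#'   two-column matrix `(n1, n2)`.
#' @examples
#' estimate_n(178, "two_sample")   # N1 = N2 = 90
#' @export
estimate_n <- function(df, design = c("one_sample", "two_sample")) {
  design <- match.arg(design)
  if (any(df < 1)) stop("df must be >= 1 to estimate a sample size")
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  if (design == "one_sample") {
    pmax(2, round_half_away(df + 1))
  } else {
    n <- pmax(2, round_half_away((df + 2) / 2))
    cbind(n1 = n, n2 = n)
  }
}

#' Default JZS Bayes factor for a t statistic
#'
#' Computes the Jeffreys–Zellner–Siow default Bayes factor comparing
#' H1: standardized effect size \eqn{\delta \sim \mathrm{Cauchy}(0, r)}
#' against H0: \eqn{\delta = 0}, from a t statistic alone. The marginal
#' likelihood under H1 is the noncentral t likelihood averaged over the
#' Cauchy prior,
#' \deqn{m_1 = \int T_\nu(t;\ \delta\sqrt{N_{\mathrm{eff}}})\,
#'       \mathrm{Cauchy}(\delta; 0, r)\, d\delta,}
#' evaluated in log space by adaptive quadrature on the arctan-transformed
#' axis \eqn{\delta = r\tan\theta} (under which the Cauchy weight becomes
#' uniform); \eqn{\nu} is the t degrees of freedom and
#' \eqn{N_{\mathrm{eff}}} the effective sample size (N for one-sample /
#' within designs, \eqn{n_1 n_2/(n_1+n_2)} for two-sample). The Bayes
#' factor is symmetric in t.
#'
#' @param t_value t statistic (finite).
#' @param design `"one_sample"` or `"two_sample"`.
#' @param n sample size: a single N for one-sample, or `c(n1, n2)` for
#'   two-sample.
#' @param rscale Cauchy prior scale (default 0.707, the conventional
#'   default placing half its mass on |effect| < 0.707).
#' @param log return the natural-log Bayes factor (never overflows).
#' @return `BF10` (or its log), a positive number; values below 1 favour
#'   the null.
#' @examples
#' jzs_bf10(2.0, "two_sample", c(90, 90))
#' @export
jzs_bf10 <- function(t_value, design = c("one_sample", "two_sample"),
                     n, rscale = 0.707, log = FALSE) {
  design <- match.arg(design)
  if (!is.finite(t_value)) stop("t must be finite")
  if (rscale <= 0) stop("rscale must be positive")
  if (design == "one_sample") {
    if (length(n) != 1 || n < 2) stop("one-sample design needs a single n >= 2")
    nu <- n - 1
    neff <- n
  } else {
    if (length(n) != 2 || any(n < 2))
      stop("two-sample design needs n = c(n1, n2), both >= 2")
    nu <- sum(n) - 2
    neff <- prod(n) / sum(n)
  }
  lb <- jzs_logbf10_core(t_value, nu, neff, rscale)
  if (log) lb else exp(lb)
}

# Log density of the noncentral t distribution, computed from its exact
# integral representation
#   f(t; nu, mu) = C(t, nu, mu) * int_0^inf y^nu exp(-(y - a)^2 / 2) dy,
#   a = mu t / sqrt(t^2 + nu),
# with the inner integral evaluated in log space on a window centred at
# its Laplace point. Stable across the full (t, nu, mu) range used here;
# the stock noncentral density has an absolute error floor around 1e-8
# that is too coarse for Bayes-factor quadrature in wide-tailed cases.
log_dnct <- function(t, nu, mu) {
  a <- mu * t / sqrt(t^2 + nu)
  ystar <- (a + sqrt(a^2 + 4 * nu)) / 2
  logh <- function(y) nu * log(y) - (y - a)^2 / 2
  m <- logh(ystar)
  logC_head <- (nu / 2) * log(nu) - nu * mu^2 / (2 * (t^2 + nu))
  # underflow exit: when the density cannot exceed exp(-600) the value is
  # zero for every caller, and the quadrature below would hit
  # catastrophic cancellation in (y - a)^2 at extreme noncentralities
  if (!is.finite(m) || logC_head + m + 10 < -600) return(-Inf)
  w <- 15 / sqrt(nu / ystar^2 + 1)
  I <- stats::integrate(function(y) exp(logh(y) - m),
                        max(ystar - w, 1e-300), ystar + w,
                        rel.tol = 1e-11, abs.tol = 0)$value
  logC <- (nu / 2) * log(nu) - nu * mu^2 / (2 * (t^2 + nu)) -
    0.5 * log(pi) - lgamma(nu / 2) - ((nu - 1) / 2) * log(2) -
    ((nu + 1) / 2) * log(t^2 + nu)
  logC + m + log(I)
}

# log BF10 for t with df nu, effective sample size neff, Cauchy scale r.
# delta = r * tan(theta) turns the Cauchy prior into Uniform(-pi/2, pi/2),
# so m1 = (1/pi) * int T_nu(t; r tan(theta) sqrt(neff)) dtheta.
jzs_logbf10_core <- function(t, nu, neff, r) {
  log_lik <- function(theta) {
    ncp <- r * tan(theta) * sqrt(neff)
    vapply(ncp, function(mu) log_dnct(t, nu, mu), numeric(1))
  }
  theta_hat <- atan(t / (sqrt(neff) * r))  # peak near the MLE of delta
  m <- log_lik(theta_hat)
  if (!is.finite(m)) stop("JZS integrand degenerate at its peak")
  f <- function(theta) exp(log_lik(theta) - m)
  # truncate where the integrand falls ~e^-34 below its peak; the
  # truncated mass is orders below the quadrature tolerance
  cut <- m - 34.5
  scan_bound <- function(to) {
    xs <- seq(theta_hat, to, length.out = 200L)
    ls <- log_lik(xs)
    idx <- which(ls < cut)
    if (length(idx)) xs[idx[1]] else to
  }
  theta_lo <- scan_bound(-pi / 2 + 1e-12)
  theta_hi <- scan_bound(pi / 2 - 1e-12)
  lo <- tryCatch(
    stats::integrate(f, theta_lo, theta_hat, rel.tol = 1e-9, abs.tol = 0,
                     subdivisions = 2000L),
    error = function(e) stop("JZS quadrature failed (lower branch): ",
                             conditionMessage(e)))
  hi <- tryCatch(
    stats::integrate(f, theta_hat, theta_hi, rel.tol = 1e-9, abs.tol = 0,
                     subdivisions = 2000L),
    error = function(e) stop("JZS quadrature failed (upper branch): ",
                             conditionMessage(e)))
  val <- lo$value + hi$value
  if (!is.finite(val) || val <= 0) stop("JZS quadrature returned a degenerate mass")
  log_m1 <- m + base::log(val) - base::log(pi)
  log_m0 <- log_dnct(t, nu, 0)
  log_m1 - log_m0
}

#' Transform a Bayes factor to a bounded probability
#'
#' Re-expresses evidence for H1 on the probability scale,
#' `p = BF10 / (BF10 + 1)`, computed stably from the log Bayes factor as
#' `plogis(log BF10)`. Bayes factors so extreme that the probability is
#' indistinguishable from 1 in double precision (log BF10 > 53 log 2) are
#' flagged as dropped and returned as `NA`, since they carry no usable
#' variation on the probability scale.
#'
#' @param bf10 Bayes factor(s); ignored when `log_bf10` is given.
#' @param log_bf10 natural-log Bayes factor(s).
#' @return numeric vector of probabilities with attribute `"dropped"`
#'   (logical): `NA` where dropped.
#' @examples
#' bf_to_prob(9)    # 0.9
#' @export
bf_to_prob <- function(bf10 = NULL, log_bf10 = NULL) {
  if (is.null(log_bf10)) {
    if (is.null(bf10)) stop("supply bf10 or log_bf10")
    if (any(bf10 <= 0)) stop("bf10 must be positive")
    log_bf10 <- base::log(bf10)
  }
  dropped <- log_bf10 > 53 * base::log(2)
  out <- stats::plogis(log_bf10)
  out[dropped] <- NA_real_
  attr(out, "dropped") <- dropped
  out
}

#' Beta(1,1) Bayes factor for two binomial proportions
#'
#' Compares H1 — two independent success rates, each with a Beta(a, b)
#' prior — against H0 — one shared rate with the same prior — by the exact
#' marginal-likelihood ratio computed with log-beta functions:
#' \deqn{\log BF_{10} = \log B(a+s_1, b+f_1) + \log B(a+s_2, b+f_2)
#'   - \log B(a, b) - \log B(a+s_1+s_2, b+f_1+f_2).}
#'
#' @param successes1,n1 successes and trials in group 1.
#' @param successes2,n2 successes and trials in group 2.
#' @param prior_a,prior_b Beta prior parameters (default 1, 1: uniform).
#' @param log return the log Bayes factor.
#' @return BF10 (or log BF10).
#' @examples
#' two_proportion_bf10(8515, 178978, 1589, 488154, log = TRUE)
#' @export
two_proportion_bf10 <- function(successes1, n1, successes2, n2,
                                prior_a = 1, prior_b = 1, log = FALSE) {
  if (successes1 < 0 || successes2 < 0 || successes1 > n1 || successes2 > n2)
    stop("invalid counts: need 0 <= successes <= n in both groups")
  f1 <- n1 - successes1
  f2 <- n2 - successes2
  lb <- lbeta(prior_a + successes1, prior_b + f1) +
    lbeta(prior_a + successes2, prior_b + f2) -
    lbeta(prior_a, prior_b) -
    lbeta(prior_a + successes1 + successes2, prior_b + f1 + f2)
  if (log) lb else exp(lb)
}

#' Two-sample JZS t-test Bayes factor from raw data
#'
#' Computes the pooled-variance two-sample t statistic from the raw group
#' values and delegates to [jzs_bf10()] with the true group sizes. An
#' optional natural-log transform (`log1p`) corrects for right skew before
#' testing (useful for citation counts).
#'
#' @param group1,group2 numeric vectors, each with >= 2 values.
#' @param rscale Cauchy prior scale (default 0.707).
#' @param log_transform apply `log(x + 1)` to both groups first.
#' @param log return the log Bayes factor.
#' @return BF10 (or log BF10).
#' @export
two_sample_jzs_ttest_bf10 <- function(group1, group2, rscale = 0.707,
                                      log_transform = FALSE, log = FALSE) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 observations")
  if (log_transform) {
    group1 <- log1p(group1)
    group2 <- log1p(group2)
  }
  n1 <- length(group1)
  n2 <- length(group2)
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    stop("degenerate pooled variance; groups must vary")
  tstat <- (mean(group1) - mean(group2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  jzs_bf10(tstat, design = "two_sample", n = c(n1, n2), rscale = rscale,
           log = log)
}

#' Score the evidential value of significant tests
#'
#' For every t test, one-df F test and Pearson r in a consistency table
#' whose recomputed p-value is at or below `alpha`, converts the statistic
#' to its t equivalent, recovers sample sizes from the degrees of freedom
#' under both design assumptions (the reported text does not say whether a
#' test was within- or between-subjects), and computes the default JZS
#' Bayes factor for each. The between-subjects (two-sample) Bayes factor
#' is transformed to the probability scale; records too extreme to
#' represent as a probability are flagged `dropped`.
#'
#' @param records a `consistency_df` (needs `recomputed_p`); or any
#'   stat-report table plus a `recomputed_p` column.
#' @param alpha recomputed-significance cutoff for inclusion (default
#'   0.05).
#' @param rscale Cauchy prior scale (default 0.707).
#' @return a `data.frame` with one row per scored test: `article_id`,
#'   `family`, `df`, `t_equivalent`, `n1_between`, `n_within`,
#'   `log_bf10_between`, `log_bf10_within`, `prob_h1`, `dropped`.
#' @export
score_evidence <- function(records, alpha = 0.05, rscale = 0.707) {
  if (is.null(records$recomputed_p))
    stop("records need a recomputed_p column; run classify_consistency first")
  eligible <- records$recomputed_p <= alpha &
    (records$family == "t" |
       (records$family == "F" & records$df1 == 1) |
       records$family == "r")
  sub <- records[which(eligible), , drop = FALSE]
  n <- nrow(sub)
  t_eq <- numeric(n)
  lb_b <- numeric(n)
  lb_w <- numeric(n)
  n_b <- integer(n)
  n_w <- integer(n)
  for (i in seq_len(n)) {
    r <- sub[i, ]
    t_eq[i] <- switch(r$family,
      t = r$statistic,
      F = f_to_t(r$statistic, r$df1),
      r = r_to_t(r$statistic, r$df2))
    nb <- estimate_n(r$df2, "two_sample")
    nw <- estimate_n(r$df2, "one_sample")
    n_b[i] <- nb[1, 1]
    n_w[i] <- nw
    lb_b[i] <- jzs_bf10(t_eq[i], "two_sample", c(nb[1, 1], nb[1, 2]),
                        rscale = rscale, log = TRUE)
    lb_w[i] <- jzs_bf10(t_eq[i], "one_sample", nw, rscale = rscale,
                        log = TRUE)
  }
  prob <- bf_to_prob(log_bf10 = lb_b)
  out <- data.frame(
    article_id = sub$article_id,
    family = sub$family,
    df = sub$df2,
    t_equivalent = t_eq,
    n1_between = n_b,
    n_within = n_w,
    log_bf10_between = lb_b,
    log_bf10_within = lb_w,
    prob_h1 = as.numeric(prob),
    dropped = attr(prob, "dropped"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
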