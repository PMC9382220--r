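test_that("statistic conversions follow the exact identities", {
  expect_equal(f_to_t(4.00), 2.00)
  expect_equal(f_to_t(0), 0)
  expect_error(f_to_t(3, df1 = 2), "one-numerator-df")
  expect_equal(r_to_t(0, 30), 0)
  expect_equal(r_to_t(0.5, 48), 4.0)   # 0.5 * sqrt(48 / 0.75)
  expect_error(r_to_t(1, 30), "< 1")
  rs <- seq(-0.9, 0.9, by = 0.15)
  expect_equal(sign(r_to_t(rs, 40)), sign(rs))
})

test_that("sample sizes are recovered from degrees of freedom", {
  expect_equal(unname(estimate_n(178, "two_sample")[1, ]), c(90, 90))
  expect_equal(estimate_n(9, "one_sample"), 10)
  # ties round away from zero: (7 + 2) / 2 = 4.5 -> 5
  expect_equal(unname(estimate_n(7, "two_sample")[1, ]), c(5, 5))
  expect_equal(estimate_n(1, "one_sample"), 2)
  expect_error(estimate_n(0.5, "one_sample"), ">= 1")
})

test_that("the JZS Bayes factor matches the g-quadrature oracle", {
  grid <- expand.grid(t = c(0, 0.8, 2.0, 5, 12, 20),
                      n = c(5, 20, 90, 500, 5000, 10000))
  max_rel <- 0
  for (i in seq_len(nrow(grid))) {
    tv <- grid$t[i]; n <- grid$n[i]
    lb_pkg <- jzs_bf10(tv, "two_sample", c(n, n), log = TRUE)
    lb_ora <- jzs_g_oracle(tv, 2 * n - 2, n / 2)
    rel <- abs(exp(lb_pkg - lb_ora) - 1)
    max_rel <- max(max_rel, rel)
    lb1_pkg <- jzs_bf10(tv, "one_sample", n, log = TRUE)
    lb1_ora <- jzs_g_oracle(tv, n - 1, n)
    max_rel <- max(max_rel, abs(exp(lb1_pkg - lb1_ora) - 1))
  }
  expect_lt(max_rel, 1e-6)
})

test_that("JZS BF favours the null at t = 0 and is symmetric", {
  expect_lt(jzs_bf10(0, "two_sample", c(50, 50)), 1)
  expect_equal(jzs_bf10(2.4, "two_sample", c(40, 40), log = TRUE),
               jzs_bf10(-2.4, "two_sample", c(40, 40), log = TRUE),
               tolerance = 1e-10)
})

test_that("JZS BF increases in |t| and concentrates with n", {
  ts <- seq(0, 8, by = 0.5)
  lbs <- vapply(ts, function(t)
    jzs_bf10(t, "two_sample", c(30, 30), log = TRUE), numeric(1))
  expect_true(all(diff(lbs) > 0))
  # evidence consistency: fixed nonzero effect grows with n, null shrinks
  ns <- c(20, 80, 320)
  alt <- vapply(ns, function(n)
    jzs_bf10(0.5 * sqrt(n / 2), "two_sample", c(n, n), log = TRUE),
    numeric(1))
  nul <- vapply(ns, function(n)
    jzs_bf10(0, "two_sample", c(n, n), log = TRUE), numeric(1))
  expect_true(all(diff(alt) > 0))
  expect_true(all(diff(nul) < 0))
})

test_that("the probability transform is exact and overflow-safe", {
  expect_equal(as.numeric(bf_to_prob(9)), 0.9)
  expect_equal(as.numeric(bf_to_prob(1)), 0.5)
  p <- bf_to_prob(log_bf10 = 800)
  expect_true(is.na(as.numeric(p)))
  expect_true(attr(p, "dropped"))
  # round trip within working precision; the probability double carries
  # about 16 digits, so exact recovery is possible while 1 - p is well
  # above machine epsilon
  lb <- c(-3, 0, 2.5, 10)
  back <- stats::qlogis(as.numeric(bf_to_prob(log_bf10 = lb)))
  expect_equal(back, lb, tolerance = 1e-10)
  expect_error(bf_to_prob(-1), "positive")
})

test_that("the Cauchy default prior places half its mass within one scale", {
  mass <- stats::pcauchy(0.707, 0, 0.707) - stats::pcauchy(-0.707, 0, 0.707)
  expect_equal(mass, 0.5, tolerance = 1e-12)
})

test_that("the beta(1,1) proportion BF separates discordant error rates", {
  lb <- two_proportion_bf10(8515, 178978, 1589, 488154, log = TRUE)
  expect_gt(lb / log(10), 16)   # published bound: BF10 > 1e16
  expect_lt(two_proportion_bf10(5, 10, 5, 10), 1)
  # symmetry under swapping the groups
  expect_equal(two_proportion_bf10(3, 20, 9, 25, log = TRUE),
               two_proportion_bf10(9, 25, 3, 20, log = TRUE),
               tolerance = 1e-12)
  expect_error(two_proportion_bf10(11, 10, 1, 10), "counts")
})

test_that("the two-sample BF composes t statistic and JZS engine", {
  set.seed(42)
  g1 <- rnorm(40, 0.6)
  g2 <- rnorm(55, 0)
  sp2 <- (39 * var(g1) + 54 * var(g2)) / 93
  tman <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 40 + 1 / 55))
  expect_equal(two_sample_jzs_ttest_bf10(g1, g2, log = TRUE),
               jzs_bf10(tman, "two_sample", c(40, 55), log = TRUE),
               tolerance = 1e-10)
  expect_lt(two_sample_jzs_ttest_bf10(g1, g1 + 0), 1.0001)
  expect_error(two_sample_jzs_ttest_bf10(rep(1, 5), rep(1, 5)),
               "variance")
})

test_that("a medium-large effect is detected in most replicates", {
  set.seed(7)
  hits <- 0L
  nrep <- 200L
  for (i in seq_len(nrep)) {
    g1 <- rnorm(200, 0.8)
    g2 <- rnorm(200, 0)
    if (two_sample_jzs_ttest_bf10(g1, g2, log = TRUE) > log(3))
      hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.95)
})

test_that("evidence scoring filters, converts and flags correctly", {
  reports <- rbind(
    stat_report("t", df2 = 178, statistic = 1.90, reported_p = 0.06,
                article_id = "a"),          # nonsignificant: excluded
    stat_report("t", df2 = 178, statistic = 2.50, reported_p = 0.01,
                article_id = "a"),
    stat_report("F", df1 = 1, df2 = 38, statistic = 9.00,
                reported_p = 0.005, p_decimals = 3, article_id = "b"),
    stat_report("F", df1 = 3, df2 = 38, statistic = 9.00,
                reported_p = 0.001, p_decimals = 3,
                article_id = "b"),          # multi-df F: excluded
    stat_report("chi2", df2 = 2, statistic = 14.14, reported_p = 0.001,
                p_decimals = 3, article_id = "b"),   # chi2: excluded
    stat_report("t", df2 = 1000, statistic = 25, reported_p = 0.001,
                p_decimals = 3, article_id = "c"))   # extreme: dropped
  ev <- score_evidence(classify_consistency(reports))
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$t_equivalent[2], 3.0)    # sqrt(9)
  expect_equal(ev$n1_between[1], 90)
  expect_equal(ev$n_within[1], 179)
  expect_false(any(ev$dropped[1:2]))
  expect_true(ev$dropped[3])
  expect_true(is.na(ev$prob_h1[3]))
  expect_equal(ev$prob_h1[1],
               stats::plogis(ev$log_bf10_between[1]))
})

test_that("between and within BF variants rank tests near-identically", {
  corp <- generate_corpus(corpus_config(n_articles = 60, seed = 14))
  ev <- score_evidence(classify_consistency(corp$tests))
  expect_gt(nrow(ev), 50)
  expect_gte(cor(ev$log_bf10_between, ev$log_bf10_within,
                 method = "spearman"), 0.95)
})
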