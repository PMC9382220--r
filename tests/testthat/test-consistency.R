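test_that("recomputed p-values match direct density integration", {
  grid <- expand.grid(
    family = c("t", "F", "chi2", "z", "r"),
    df2 = c(5, 30, 178, 1000),
    statistic = c(0.5, 1.9, 3.2),
    stringsAsFactors = FALSE
  )
  grid$df1 <- ifelse(grid$family == "F", 2, NA)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$family == "r") {
      # r in (-1, 1): reuse the statistic as a correlation scaled down
      r <- g$statistic / 4
      p_pkg <- recompute_p_one("r", NA, g$df2, r, "two")
      tval <- r * sqrt(g$df2 / (1 - r^2))
      p_ora <- integrate_tail_p("t", NA, g$df2, tval)
    } else {
      p_pkg <- recompute_p_one(g$family, g$df1, g$df2, g$statistic, "two")
      p_ora <- integrate_tail_p(g$family, g$df1, g$df2, g$statistic)
    }
    expect_equal(p_pkg, p_ora, tolerance = 1e-8,
                 label = paste(g$family, g$df2, g$statistic))
  }
})

test_that("recomputed p behaves at the reference points", {
  # the canonical marginal case: t of 1.90 on 178 df exceeds 0.05
  p <- recompute_p(stat_report("t", df2 = 178, statistic = 1.90,
                               reported_p = 0.06))
  expect_gt(p, 0.05)
  expect_equal(p, 0.059, tolerance = 1e-2)
  expect_equal(recompute_p(stat_report("t", df2 = 7, statistic = 0,
                                       reported_p = 1)), 1.0)
  expect_equal(recompute_p(stat_report("r", df2 = 50, statistic = 0,
                                       reported_p = 1)), 1.0)
  # F(1, nu) equals the square of t(nu)
  pF <- recompute_p(stat_report("F", df1 = 1, df2 = 38, statistic = 4.00,
                                reported_p = 0.05))
  pt <- recompute_p(stat_report("t", df2 = 38, statistic = 2.00,
                                reported_p = 0.05))
  expect_equal(pF, pt, tolerance = 1e-12)
})

test_that("recomputed p is strictly decreasing in |statistic|", {
  stats_grid <- seq(0.1, 6, by = 0.35)
  for (fam in c("t", "z")) {
    ps <- vapply(stats_grid, function(s)
      recompute_p_one(fam, NA, 25, s, "two"), numeric(1))
    expect_true(all(diff(ps) < 0), label = fam)
  }
  # chi2/F: keep df small so the whole grid sits inside the mass
  psC <- vapply(stats_grid, function(s)
    recompute_p_one("chi2", NA, 3, s, "two"), numeric(1))
  expect_true(all(diff(psC) < 0))
  psF <- vapply(stats_grid, function(s)
    recompute_p_one("F", 3, 8, s, "two"), numeric(1))
  expect_true(all(diff(psF) < 0))
})

test_that("classification separates consistency, inconsistency, error", {
  r <- function(p_cmp, p_rep, dec = 2)
    stat_report("t", df2 = 178, statistic = 1.90, p_comparator = p_cmp,
                reported_p = p_rep, p_decimals = dec)
  # recomputed p is ~0.0590
  over <- classify_consistency(r("eq", 0.04))
  expect_equal(over$label, "decision_error")
  expect_equal(over$error_direction, "overclaim")
  ok <- classify_consistency(r("eq", 0.06))
  expect_equal(ok$label, "consistent")
  bound <- classify_consistency(stat_report("t", df2 = 1000,
                                            statistic = 5,
                                            p_comparator = "lt",
                                            reported_p = 0.001,
                                            p_decimals = 3))
  expect_equal(bound$label, "consistent")
  # wrong but same side of alpha: inconsistency, not a decision error
  inc <- classify_consistency(r("eq", 0.30))
  expect_equal(inc$label, "inconsistency")
  expect_equal(inc$error_direction, "none")
  # underclaim: significant statistic reported as p > .05
  under <- classify_consistency(stat_report("t", df2 = 100,
                                            statistic = 3.5,
                                            p_comparator = "gt",
                                            reported_p = 0.05))
  expect_equal(under$error_direction, "underclaim")
})

test_that("a reported p = .05 just above alpha counts as rounding", {
  # recomputed p ~ 0.0524 rounds to .05: consistent, not an error
  rep <- stat_report("t", df2 = 300, statistic = 1.945,
                     p_comparator = "eq", reported_p = 0.05)
  out <- classify_consistency(rep)
  expect_gt(out$recomputed_p, 0.05)
  expect_lt(out$recomputed_p, 0.055)
  expect_equal(out$label, "consistent")
})

test_that("moving alpha across the recomputed p flips error status", {
  rep <- stat_report("t", df2 = 178, statistic = 1.90,
                     p_comparator = "eq", reported_p = 0.04)
  hi <- classify_consistency(rep, alpha = 0.05)   # p_rec > alpha
  lo <- classify_consistency(rep, alpha = 0.10)   # p_rec < alpha
  expect_equal(hi$label, "decision_error")
  expect_false(lo$label == "decision_error")
})

test_that("labels are exhaustive and exclusive over random reports", {
  reports <- random_stat_reports(300, seed = 21)
  out <- classify_consistency(reports)
  expect_true(all(out$label %in%
                    c("consistent", "inconsistency", "decision_error")))
  expect_equal(out$label == "decision_error",
               out$error_direction != "none")
})

test_that("article summaries count tests and errors", {
  reports <- rbind(
    stat_report("t", df2 = 178, statistic = 1.90, reported_p = 0.06,
                article_id = "A"),
    stat_report("t", df2 = 60, statistic = 2.8, reported_p = 0.007,
                p_decimals = 3, article_id = "A"),
    stat_report("t", df2 = 178, statistic = 1.90, reported_p = 0.04,
                article_id = "A"))
  out <- summarize_article(classify_consistency(reports))
  expect_equal(out$n_tests, 3)
  expect_equal(out$n_inconsistencies, 1)
  expect_equal(out$n_decision_errors, 1)
  expect_true(out$has_decision_error)

  clean <- summarize_article(
    classify_consistency(reports[1:2, ]), article_id = "A")
  expect_equal(clean$n_decision_errors, 0)
  expect_false(clean$has_decision_error)
})

test_that("corpus filtering drops short articles and recounts chi2", {
  mk <- function(id, fams) {
    do.call(rbind, lapply(fams, function(f)
      if (f == "chi2")
        stat_report("chi2", df2 = 2, statistic = 8, reported_p = 0.02,
                    article_id = id)
      else stat_report("t", df2 = 30, statistic = 2.5, reported_p = 0.02,
                       article_id = id)))
  }
  recs <- classify_consistency(rbind(mk("one", "t"),
                                     mk("two", c("t", "t")),
                                     mk("mix", c("t", "chi2"))))
  kept <- filter_corpus(recs, min_tests = 2, include_chi2 = TRUE)
  expect_setequal(unique(kept$article_id), c("two", "mix"))
  dropped_chi2 <- filter_corpus(recs, min_tests = 2, include_chi2 = FALSE)
  expect_setequal(unique(dropped_chi2$article_id), "two")
  # idempotence
  again <- filter_corpus(dropped_chi2, min_tests = 2,
                         include_chi2 = FALSE)
  expect_equal(nrow(again), nrow(dropped_chi2))
})

test_that("suspect chi-squared records are flagged by the df/N heuristic", {
  recs <- classify_consistency(rbind(
    stat_report("chi2", df2 = 170, reported_n = 170L, statistic = 14,
                reported_p = 0.001, p_decimals = 3, article_id = "m"),
    stat_report("chi2", df2 = 2, reported_n = 170L, statistic = 14.14,
                reported_p = 0.001, p_decimals = 3, article_id = "m")))
  out <- filter_corpus(recs, min_tests = 1)
  expect_equal(out$chi2_suspect, c(TRUE, FALSE))
})

test_that("the cross-tabulation reproduces published error rates", {
  ct <- crosstab_from_counts(178978, 8515, 488154, 1589)
  expect_equal(ct$rate_overclaim, 4.76, tolerance = 0.005)
  expect_equal(ct$rate_underclaim, 100 * 1589 / 488154, tolerance = 1e-12)
  expect_equal(round(ct$rate_underclaim, 1), 0.3)
  none <- crosstab_from_counts(100, 0, 100, 0)
  expect_equal(none$rate_overclaim, 0)
  expect_equal(none$rate_underclaim, 0)
})

test_that("cross_tabulate agrees with direct counting on records", {
  reports <- random_stat_reports(400, seed = 31)
  recs <- classify_consistency(reports)
  ct <- cross_tabulate(recs)
  expect_equal(ct$n_recomputed_nonsig + ct$n_recomputed_sig, nrow(recs))
  expect_equal(ct$n_recomputed_nonsig_reported_sig,
               sum(recs$error_direction == "overclaim"))
  expect_equal(ct$n_recomputed_sig_reported_nonsig,
               sum(recs$error_direction == "underclaim"))
})
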