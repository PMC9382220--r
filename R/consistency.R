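#' Recompute p-values from reported statistics
#'
#' Recomputes each report's p-value from its test statistic and degrees of
#' freedom under the reference distribution of the test family: central t,
#' central F, Pearson r via the exact t transform
#' \eqn{t = r \sqrt{df / (1 - r^2)}}, central chi-squared, or the standard
#' normal for z. t, r and z are two-tailed by default (the one-tailed
#' probability is doubled); F and chi-squared are inherently one-tailed.
#' Results are clamped into `(0, 1]`.
#'
#' @param reports a stat-report `data.frame` (see [stat_report()]).
#' @param tails `"two"` (default) or `"one"`; applies to t, r and z only.
#'   When `tails` is `"auto"`, each row's `one_tailed` flag decides.
#' @return numeric vector of recomputed p-values, one per row.
#' @examples
#' recompute_p(stat_report("t", df2 = 178, statistic = 1.90,
#'                         p_comparator = "eq", reported_p = 0.06))
#' @export
recompute_p <- function(reports, tails = c("auto", "two", "one")) {
  tails <- match.arg(tails)
  validate_stat_reports(reports)
  n <- nrow(reports)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- reports[i, ]
    row_tails <- switch(tails,
      two = "two", one = "one",
      auto = if (isTRUE(r$one_tailed)) "one" else "two")
    out[i] <- recompute_p_one(r$family, r$df1, r$df2, r$statistic, row_tails)
  }
  out
}

recompute_p_one <- function(family, df1, df2, statistic, tails) {
  p <- switch(family,
    t = {
      if (!is.finite(df2)) stop("df2 missing for t report")
      p1 <- stats::pt(abs(statistic), df = df2, lower.tail = FALSE)
      if (tails == "two") 2 * p1 else p1
    },
    z = {
      p1 <- stats::pnorm(abs(statistic), lower.tail = FALSE)
      if (tails == "two") 2 * p1 else p1
    },
    r = {
      if (!is.finite(df2)) stop("df2 missing for r report")
      if (abs(statistic) >= 1)
        stop("r statistic must satisfy |r| < 1 to recompute p")
      tval <- statistic * sqrt(df2 / (1 - statistic^2))
      p1 <- stats::pt(abs(tval), df = df2, lower.tail = FALSE)
      if (tails == "two") 2 * p1 else p1
    },
    F = {
      if (!is.finite(df1) || !is.finite(df2))
        stop("df1/df2 missing for F report")
      stats::pf(statistic, df1 = df1, df2 = df2, lower.tail = FALSE)
    },
    chi2 = {
      if (!is.finite(df2)) stop("df missing for chi2 report")
      stats::pchisq(statistic, df = df2, lower.tail = FALSE)
    },
    stop("unknown family ", family)
  )
  min(max(p, .Machine$double.xmin), 1)
}

#' Classify reporting consistency and decision errors
#'
#' Compares each report's stated p-value against the p recomputed from its
#' statistic and degrees of freedom, under a rounding-aware policy, and
#' labels it:
#'
#' * `consistent` — the reported comparator/value is compatible with the
#'   recomputed p. For `p = v` at `d` decimals, compatible means
#'   `|p_rec - v| <= 0.5 * 10^-d`; for `p < v`, `p_rec < v`; for `p > v`,
#'   `p_rec > v`; for `ns`, `p_rec > alpha`.
#' * `inconsistency` — incompatible, but reported and recomputed
#'   significance at `alpha` agree.
#' * `decision_error` — reported and recomputed significance disagree:
#'   an *overclaim* when the result was reported significant
#'   (reported p <= alpha, including the `p = .05` boundary, or a `<` bound
#'   at or below alpha) but the recomputed p exceeds alpha; an *underclaim*
#'   for the reverse.
#'
#' A reported `p = .05` whose recomputed value lies just above 0.05 but
#' rounds back to .05 is treated as consistent (rounding), not as a
#' decision error.
#'
#' @param reports a stat-report `data.frame`.
#' @param alpha significance threshold (default 0.05).
#' @param tails tail convention passed to [recompute_p()].
#' @return the input with columns `recomputed_p`, `label`,
#'   `error_direction` appended; class `"consistency_df"`.
#' @export
classify_consistency <- function(reports, alpha = 0.05,
                                 tails = c("auto", "two", "one")) {
  tails <- match.arg(tails)
  p_rec <- recompute_p(reports, tails = tails)
  n <- nrow(reports)
  label <- character(n)
  direction <- character(n)
  for (i in seq_len(n)) {
    r <- reports[i, ]
    compatible <- p_compatible(r$p_comparator, r$reported_p, r$p_decimals,
                               p_rec[i], alpha)
    rep_sig <- reported_significant(r$p_comparator, r$reported_p, alpha)
    rec_sig <- p_rec[i] <= alpha
    if (compatible) {
      label[i] <- "consistent"; direction[i] <- "none"
    } else if (rep_sig == rec_sig) {
      label[i] <- "inconsistency"; direction[i] <- "none"
    } else {
      label[i] <- "decision_error"
      direction[i] <- if (rep_sig) "overclaim" else "underclaim"
    }
  }
  out <- reports
  out$recomputed_p <- p_rec
  out$label <- label
  out$error_direction <- direction
  class(out) <- c("consistency_df", "data.frame")
  out
}

p_compatible <- function(comparator, reported_p, p_decimals, p_rec, alpha) {
  switch(comparator,
    eq = abs(p_rec - reported_p) <= 0.5 * 10^(-p_decimals) + 1e-12,
    lt = p_rec < reported_p,
    gt = p_rec > reported_p,
    ns = p_rec > alpha
  )
}

reported_significant <- function(comparator, reported_p, alpha) {
  switch(comparator,
    eq = reported_p <= alpha,
    lt = reported_p <= alpha,
    gt = FALSE,
    ns = FALSE
  )
}

#' Summarize consistency records to the article level
#'
#' Counts tests, inconsistencies (including decision errors) and decision
#' errors for one article's records.
#'
#' @param records a `consistency_df` (output of [classify_consistency()]);
#'   all rows must share one article.
#' @param article_id identifier; defaults to the records' own.
#' @return one-row `data.frame` with `article_id`, `n_tests`,
#'   `n_inconsistencies`, `n_decision_errors`, `has_decision_error`.
#' @export
summarize_article <- function(records, article_id = NULL) {
  if (is.null(article_id)) {
    ids <- unique(records$article_id)
    article_id <- if (length(ids) == 1) ids else NA_character_
    if (length(ids) > 1)
      stop("records span multiple articles; supply article_id per group")
  }
  n_err <- sum(records$label == "decision_error")
  data.frame(
    article_id = as.character(article_id),
    n_tests = nrow(records),
    n_inconsistencies = sum(records$label %in%
                              c("inconsistency", "decision_error")),
    n_decision_errors = n_err,
    has_decision_error = n_err >= 1,
    stringsAsFactors = FALSE
  )
}

#' Summarize a multi-article record table
#'
#' Applies [summarize_article()] per `article_id`.
#'
#' @param records a `consistency_df` with an `article_id` column.
#' @return a `data.frame` with one row per article.
#' @export
summarize_articles <- function(records) {
  parts <- split(records, records$article_id)
  out <- do.call(rbind, lapply(names(parts), function(id)
    summarize_article(parts[[id]], article_id = id)))
  rownames(out) <- NULL
  out
}

#' Filter a corpus by minimum test count
#'
#' Drops articles reporting fewer than `min_tests` statistical tests
#' (articles with a single test are typically commentaries or editorials
#' and carry no between-test variability). When `include_chi2` is `FALSE`,
#' chi-squared records — whose degrees of freedom are sometimes miscoded as
#' the sample size — are removed first and `n_tests` is recounted before
#' the threshold is applied. Chi-squared rows carrying a reported N with
#' `df2 > 0.5 * reported_n` are flagged as suspect either way. The filter
#' is idempotent.
#'
#' @param records a `consistency_df` with `article_id` (per-test rows).
#' @param min_tests minimum tests per article (default 2).
#' @param include_chi2 keep chi-squared records? (default `TRUE`).
#' @return filtered per-test records, with a `chi2_suspect` column.
#' @export
filter_corpus <- function(records, min_tests = 2, include_chi2 = TRUE) {
  records$chi2_suspect <- records$family == "chi2" &
    !is.na(records$reported_n) &
    records$df2 > 0.5 * records$reported_n
  if (!include_chi2) {
    records <- records[records$family != "chi2", , drop = FALSE]
  }
  counts <- table(records$article_id)
  keep_ids <- names(counts)[counts >= min_tests]
  out <- records[records$article_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate reported versus recomputed significance
#'
#' Partitions records by recomputed significance at `alpha` and counts the
#' discordant reports in each stratum: among tests whose recomputed p
#' exceeds alpha, the fraction reported as significant (overclaims); among
#' tests whose recomputed p is at or below alpha, the fraction reported as
#' nonsignificant (underclaims). Rates are percentages.
#'
#' @param records a `consistency_df`.
#' @param alpha significance threshold (default 0.05).
#' @return an object of class `"error_crosstab"`: a list with counts
#'   `n_recomputed_nonsig`, `n_recomputed_nonsig_reported_sig`,
#'   `n_recomputed_sig`, `n_recomputed_sig_reported_nonsig` and rates
#'   `rate_overclaim`, `rate_underclaim`.
#' @export
cross_tabulate <- function(records, alpha = 0.05) {
  rec_sig <- records$recomputed_p <= alpha
  over <- records$label == "decision_error" &
    records$error_direction == "overclaim"
  under <- records$label == "decision_error" &
    records$error_direction == "underclaim"
  crosstab_from_counts(
    n_nonsig = sum(!rec_sig),
    n_nonsig_rep_sig = sum(over),
    n_sig = sum(rec_sig),
    n_sig_rep_nonsig = sum(under)
  )
}

#' Build a cross-tabulation from raw counts
#'
#' Constructs the reported-vs-recomputed significance cross-tab directly
#' from the four counts, e.g. from a published contingency table.
#'
#' @param n_nonsig tests with recomputed p above alpha.
#' @param n_nonsig_rep_sig of those, reported as significant (overclaims).
#' @param n_sig tests with recomputed p at or below alpha.
#' @param n_sig_rep_nonsig of those, reported nonsignificant (underclaims).
#' @return an `"error_crosstab"` object (see [cross_tabulate()]).
#' @examples
#' crosstab_from_counts(178978, 8515, 488154, 1589)
#' @export
crosstab_from_counts <- function(n_nonsig, n_nonsig_rep_sig,
                                 n_sig, n_sig_rep_nonsig) {
  stopifnot(n_nonsig_rep_sig <= n_nonsig, n_sig_rep_nonsig <= n_sig)
  out <- list(
    n_recomputed_nonsig = n_nonsig,
    n_recomputed_nonsig_reported_sig = n_nonsig_rep_sig,
    n_recomputed_sig = n_sig,
    n_recomputed_sig_reported_nonsig = n_sig_rep_nonsig,
    rate_overclaim = if (n_nonsig > 0) 100 * n_nonsig_rep_sig / n_nonsig else 0,
    rate_underclaim = if (n_sig > 0) 100 * n_sig_rep_nonsig / n_sig else 0
  )
  class(out) <- "error_crosstab"
  out
}

#' @export
print.error_crosstab <- function(x, ...) {
  cat("Reported vs recomputed significance cross-tabulation\n")
  cat(sprintf("  recomputed p > alpha : %d, of which reported significant: %d (%.2f%%)\n",
              x$n_recomputed_nonsig, x$n_recomputed_nonsig_reported_sig,
              x$rate_overclaim))
  cat(sprintf("  recomputed p <= alpha: %d, of which reported nonsignificant: %d (%.2f%%)\n",
              x$n_recomputed_sig, x$n_recomputed_sig_reported_nonsig,
              x$rate_underclaim))
  invisible(x)
}

#' Write a cross-tabulation as JSON
#'
#' @param x an `"error_crosstab"`.
#' @param path output path.
#' @export
write_crosstab_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
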