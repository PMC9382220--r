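#' Construct a table of statistical test reports
#'
#' A stat-report table holds one row per reported null-hypothesis test, in
#' the form the test appears in a manuscript: the test family, degrees of
#' freedom, the statistic value, and the reported p-value together with its
#' comparator ("=", "<", ">", or "ns"). It is the common currency between
#' the APA-text parser, the consistency checker and the evidence scorer.
#'
#' @param family character vector, one of `"t"`, `"F"`, `"r"`, `"chi2"`,
#'   `"z"`.
#' @param df1 numerator degrees of freedom (F tests only; `NA` otherwise).
#' @param df2 denominator/main degrees of freedom (t, F, r, chi2; `NA` for
#'   z).
#' @param reported_n sample size captured from a chi-squared "N = ..."
#'   clause, `NA` when absent.
#' @param statistic the reported test statistic.
#' @param p_comparator one of `"eq"`, `"lt"`, `"gt"`, `"ns"`.
#' @param reported_p the reported p-value in `[0, 1]`; must be `NA` exactly
#'   when `p_comparator` is `"ns"`.
#' @param p_decimals number of decimals the p-value was reported with
#'   (drives rounding-aware consistency checks).
#' @param one_tailed logical; `TRUE` when the text flags a one-tailed test.
#' @param article_id optional article identifier.
#'
#' @return A `data.frame` with one row per report and class
#'   `"stat_report_df"`.
#' @examples
#' stat_report("t", df2 = 178, statistic = 1.90,
#'             p_comparator = "eq", reported_p = 0.06)
#' @export
stat_report <- function(family, df1 = NA_real_, df2 = NA_real_,
                        reported_n = NA_integer_, statistic,
                        p_comparator = "eq", reported_p = NA_real_,
                        p_decimals = 2L, one_tailed = FALSE,
                        article_id = NA_character_) {
  df <- data.frame(
    article_id = as.character(article_id),
    family = as.character(family),
    df1 = as.numeric(df1),
    df2 = as.numeric(df2),
    reported_n = as.integer(reported_n),
    statistic = as.numeric(statistic),
    p_comparator = as.character(p_comparator),
    reported_p = as.numeric(reported_p),
    p_decimals = as.integer(p_decimals),
    one_tailed = as.logical(one_tailed),
    source_start = NA_integer_,
    source_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  validate_stat_reports(df)
  class(df) <- c("stat_report_df", "data.frame")
  df
}

#' Validate a stat-report table
#'
#' Checks the structural invariants of a stat-report table and stops with a
#' message naming the offending field on the first violation: families must
#' be known, F tests need a numerator df, correlations must satisfy
#' |r| <= 1, reported p-values must lie in `[0, 1]` and be absent exactly
#' when the comparator is `"ns"`, and degrees of freedom must be positive
#' where present.
#'
#' @param reports a stat-report `data.frame`.
#' @return `reports`, invisibly, when valid.
#' @export
validate_stat_reports <- function(reports) {
  stopifnot(is.data.frame(reports))
  fam <- reports$family
  bad <- !fam %in% c("t", "F", "r", "chi2", "z")
  if (any(bad)) stop("family: unknown test family ", fam[bad][1])
  if (any(fam == "F" & !is.finite(reports$df1)))
    stop("df1: F reports require a numerator df")
  if (any(fam %in% c("t", "F", "r", "chi2") & !is.finite(reports$df2)))
    stop("df2: missing degrees of freedom for a ",
         fam[fam %in% c("t", "F", "r", "chi2") & !is.finite(reports$df2)][1],
         " report")
  if (any(is.finite(reports$df2) & reports$df2 <= 0))
    stop("df2: degrees of freedom must be positive")
  if (any(fam == "r" & abs(reports$statistic) > 1))
    stop("statistic: |r| must not exceed 1")
  if (any(fam %in% c("F", "chi2") & reports$statistic < 0))
    stop("statistic: ", fam[fam %in% c("F", "chi2") & reports$statistic < 0][1],
         " statistics are nonnegative")
  cmp <- reports$p_comparator
  if (any(!cmp %in% c("eq", "lt", "gt", "ns")))
    stop("p_comparator: must be eq, lt, gt or ns")
  p <- reports$reported_p
  if (any(cmp == "ns" & !is.na(p)))
    stop("reported_p: must be absent when p_comparator is ns")
  if (any(cmp != "ns" & is.na(p)))
    stop("reported_p: required unless p_comparator is ns")
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("reported_p: must lie in [0, 1]")
  if (any(reports$p_decimals < 1L, na.rm = TRUE))
    stop("p_decimals: must be >= 1")
  invisible(reports)
}

# Family-specific regular expressions for the APA core dialect. Each entry
# gives the pattern and the capture-group roles. Statistic signs: t/r/z may
# be negative; F and chi2 may not. The p clause is shared.
.p_clause <- "p\\s*(=|<|>)\\s*(0?\\.\\d+|1(?:\\.0+)?)|\\bns\\b|\\bn\\.s\\.(?:\\B|\\b)"
.num <- "\\d+(?:\\.\\d+)?"
.snum <- "[+-]?\\d*\\.?\\d+"

.apa_patterns <- list(
  t = list(
    regex = paste0("\\bt\\s*\\(\\s*(", .num, ")\\s*\\)\\s*=\\s*(", .snum,
                   ")\\s*,\\s*(?:", .p_clause, ")"),
    roles = c("df2", "statistic", "p_comparator", "reported_p")
  ),
  F = list(
    regex = paste0("\\bF\\s*\\(\\s*(", .num, ")\\s*,\\s*(", .num,
                   ")\\s*\\)\\s*=\\s*(", .num, ")\\s*,\\s*(?:", .p_clause, ")"),
    roles = c("df1", "df2", "statistic", "p_comparator", "reported_p")
  ),
  r = list(
    regex = paste0("\\br\\s*\\(\\s*(", .num, ")\\s*\\)\\s*=\\s*(", .snum,
                   ")\\s*,\\s*(?:", .p_clause, ")"),
    roles = c("df2", "statistic", "p_comparator", "reported_p")
  ),
  chi2 = list(
    regex = paste0("(?:χ²|χ2|chi2|X2|x2)\\s*\\(\\s*(", .num,
                   ")\\s*(?:,\\s*N\\s*=\\s*(\\d+)\\s*)?\\)\\s*=\\s*(", .num,
                   ")\\s*,\\s*(?:", .p_clause, ")"),
    roles = c("df2", "reported_n", "statistic", "p_comparator", "reported_p")
  ),
  z = list(
    regex = paste0("\\bz\\s*=\\s*(", .snum, ")\\s*,\\s*(?:", .p_clause, ")"),
    roles = c("statistic", "p_comparator", "reported_p")
  )
)

#' Extract APA-formatted test reports from text
#'
#' Scans plain text for APA-style test reports such as
#' `"t(178) = 1.90, p = .06"`, `"F(1, 38) = 4.00, p < .05"`,
#' `"chi2(2, N = 170) = 14.14, p < .001"` or `"z = 2.03, p = .04"` and
#' returns them as a stat-report table in textual order. Text that does not
#' match the grammar is ignored; overlapping candidate matches are resolved
#' in favour of the earliest (then longest) match. A "one-tailed" or
#' "one-sided" marker within 40 characters after a match sets the report's
#' `one_tailed` flag.
#'
#' Degrees of freedom are required for t, F, r and chi-squared reports (a
#' bare `"t = 1.9, p = .06"` does not parse); leading zeros on p-values are
#' optional; `ns` / `n.s.` are accepted in place of a numeric p.
#'
#' @param text a character scalar (or vector, concatenated with newlines).
#' @param article_id optional identifier stored on every extracted row.
#' @return A stat-report `data.frame` with `source_start`/`source_end`
#'   character offsets; zero rows when nothing matches.
#' @examples
#' extract_stat_reports("We found t(178) = 1.90, p = .06 overall.")
#'
#' path <- system.file("extdata", "example_article.txt",
#'                     package = "bibquality")
#' extract_stat_reports(readLines(path))
#' @export
extract_stat_reports <- function(text, article_id = NA_character_) {
  text <- paste(text, collapse = "\n")
  hits <- list()
  for (fam in names(.apa_patterns)) {
    pat <- .apa_patterns[[fam]]
    m <- gregexpr(pat$regex, text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    for (i in seq_along(m)) {
      grp <- function(j) {
        if (cs[i, j] == 0L) return(NA_character_)
        substr(text, cs[i, j], cs[i, j] + cl[i, j] - 1L)
      }
      ng <- ncol(cs)
      # last two capture groups are always comparator and p value
      vals <- vapply(seq_len(ng), grp, character(1))
      named <- vals[seq_len(ng - 2L)]
      names(named) <- pat$roles[seq_len(ng - 2L)]
      role_val <- function(nm) {
        if (nm %in% names(named)) named[[nm]] else NA_character_
      }
      cmp_raw <- vals[ng - 1L]
      p_raw <- vals[ng]
      whole <- substr(text, m[i], m[i] + attr(m, "match.length")[i] - 1L)
      if (is.na(cmp_raw)) {
        # matched the ns alternative
        cmp <- "ns"; p_val <- NA_real_; p_dec <- 1L
      } else {
        cmp <- c("=" = "eq", "<" = "lt", ">" = "gt")[[cmp_raw]]
        p_val <- as.numeric(p_raw)
        p_dec <- if (grepl("\\.", p_raw)) {
          nchar(sub("^[^.]*\\.", "", p_raw))
        } else 1L
      }
      tail_ctx <- substr(text, m[i] + attr(m, "match.length")[i],
                         m[i] + attr(m, "match.length")[i] + 40L)
      hits[[length(hits) + 1L]] <- data.frame(
        article_id = article_id,
        family = fam,
        df1 = as.numeric(role_val("df1")),
        df2 = as.numeric(role_val("df2")),
        reported_n = as.integer(role_val("reported_n")),
        statistic = as.numeric(role_val("statistic")),
        p_comparator = cmp,
        reported_p = p_val,
        p_decimals = p_dec,
        one_tailed = grepl("one[- ](tailed|sided)", tail_ctx),
        source_start = as.integer(m[i]),
        source_end = as.integer(m[i] + attr(m, "match.length")[i] - 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) return(empty_stat_reports())
  out <- do.call(rbind, hits)
  out <- out[order(out$source_start, -out$source_end), , drop = FALSE]
  # drop overlaps: keep a match only if it starts after the previous kept end
  keep <- logical(nrow(out))
  last_end <- 0L
  for (i in seq_len(nrow(out))) {
    if (out$source_start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- out$source_end[i]
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  # re-scan the one-tailed marker in a window clipped at the next report,
  # so a marker never attaches to more than one report
  n <- nrow(out)
  for (i in seq_len(n)) {
    w_end <- out$source_end[i] + 40L
    if (i < n) w_end <- min(w_end, out$source_start[i + 1L] - 1L)
    ctx <- substr(text, out$source_end[i] + 1L, w_end)
    out$one_tailed[i] <- grepl("one[- ](tailed|sided)", ctx)
  }
  class(out) <- c("stat_report_df", "data.frame")
  out
}

empty_stat_reports <- function() {
  out <- data.frame(
    article_id = character(0), family = character(0), df1 = numeric(0),
    df2 = numeric(0), reported_n = integer(0), statistic = numeric(0),
    p_comparator = character(0), reported_p = numeric(0),
    p_decimals = integer(0), one_tailed = logical(0),
    source_start = integer(0), source_end = integer(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stat_report_df", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Render stat reports back to APA text
#'
#' Inverse of [extract_stat_reports()]: formats each row of a stat-report
#' table as an APA-style string, e.g. `"t(178) = 1.90, p = .06"`. P-values
#' are printed at the row's `p_decimals` precision in APA style (no leading
#' zero); statistics are printed at 2 decimals. Rendered strings re-parse to
#' the original rows (round-trip property).
#'
#' @param reports a stat-report `data.frame` satisfying the invariants.
#' @return character vector, one string per row.
#' @export
render_stat_report <- function(reports) {
  validate_stat_reports(reports)
  n <- nrow(reports)
  out <- character(n)
  for (i in seq_len(n)) {
    r <- reports[i, ]
    stat_txt <- formatC(r$statistic, format = "f", digits = 2)
    head_txt <- switch(r$family,
      t = sprintf("t(%s) = %s", fmt_df(r$df2), stat_txt),
      F = sprintf("F(%s, %s) = %s", fmt_df(r$df1), fmt_df(r$df2), stat_txt),
      r = sprintf("r(%s) = %s", fmt_df(r$df2), stat_txt),
      chi2 = if (is.finite(r$reported_n) && !is.na(r$reported_n)) {
        sprintf("chi2(%s, N = %d) = %s", fmt_df(r$df2), r$reported_n, stat_txt)
      } else {
        sprintf("chi2(%s) = %s", fmt_df(r$df2), stat_txt)
      },
      z = sprintf("z = %s", stat_txt)
    )
    p_txt <- if (r$p_comparator == "ns") {
      "ns"
    } else {
      cmp <- c(eq = "=", lt = "<", gt = ">")[[r$p_comparator]]
      pv <- formatC(r$reported_p, format = "f", digits = r$p_decimals)
      pv <- sub("^0\\.", ".", pv)
      sprintf("p %s %s", cmp, pv)
    }
    tail_txt <- if (isTRUE(r$one_tailed)) ", one-tailed" else ""
    out[i] <- sprintf("%s, %s%s", head_txt, p_txt, tail_txt)
  }
  out
}

fmt_df <- function(x) {
  if (x == round(x)) sprintf("%d", as.integer(x)) else
    formatC(x, format = "f", digits = 1)
}

#' Read / write stat-report tables as CSV
#'
#' Plain RFC-4180 CSV with one column per stat-report field and a header
#' row.
#'
#' @param path file path.
#' @param reports a stat-report `data.frame` (for writing).
#' @return `read_stat_reports` returns a stat-report `data.frame`.
#' @export
read_stat_reports <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$family <- as.character(out$family)
  out$p_comparator <- as.character(out$p_comparator)
  validate_stat_reports(out)
  class(out) <- c("stat_report_df", "data.frame")
  out
}

#' @rdname read_stat_reports
#' @export
write_stat_reports <- function(reports, path) {
  validate_stat_reports(reports)
  utils::write.csv(reports, path, row.names = FALSE, na = "")
  invisible(path)
}
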