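#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()]: Pearson's r with the two-sided
#' p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, both with non-zero
#'   variance. Pairs with an `NA` in either vector are dropped
#'   (pairwise-complete observations).
#' @return List with `r`, `p`, `n` (pairs used).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Load the packaged platform-comparison table
#'
#' The 25-row mock-community comparison table (17 HM782D genera + 8 D6305
#' genera): per-genus relative read proportions for the Reference design and
#' the MiSeq, R9 and R9.4 runs, plus the three coverage-bias columns. `ND`
#' cells (bias undefined because a genus went undetected) are read as `NA`.
#' Undetected proportions are kept as 0, as printed.
#'
#' @return Data frame with columns `community`, `taxon`, `reference`,
#'   `miseq`, `r9`, `r94`, `bias_miseq`, `bias_r9`, `bias_r94`.
#' @export
load_platform_table <- function() {
  path <- system.file("extdata", "table3_comparison.tsv",
                      package = "rrnprofile", mustWork = TRUE)
  read.delim(path, na.strings = "ND", check.names = FALSE)
}

#' Column summaries of a comparison table
#'
#' Average, median, min and max per numeric column, with `NA` (`ND`) cells
#' excluded; the count of cells used is reported per column. Summaries are
#' computed at full precision; rounding happens only when printing.
#'
#' @param tbl A comparison table, e.g. from [load_platform_table()].
#' @param columns Columns to summarise (default: all numeric columns).
#' @return List with `summary` (data frame, one row per statistic) and
#'   `n_used` (named integer vector).
#' @export
column_summaries <- function(tbl, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  }
  if (length(columns) == 0) stop("no numeric columns to summarise")
  stats_fun <- list(average = mean, median = median, min = min, max = max)
  vals <- lapply(columns, function(col) {
    v <- tbl[[col]]
    v <- v[!is.na(v)]
    if (length(v) == 0) stop("column ", col, " is all ND")
    vapply(stats_fun, function(f) f(v), numeric(1))
  })
  names(vals) <- columns
  summary <- data.frame(statistic = names(stats_fun))
  for (col in columns) summary[[col]] <- vals[[col]]
  n_used <- vapply(columns, function(col) sum(!is.na(tbl[[col]])), integer(1))
  list(summary = summary, n_used = n_used)
}

#' Platform-comparison statistics report
#'
#' Computes the five Pearson correlations over the paired rows of a
#' comparison table -- each platform against the reference design, and each
#' MinION chemistry against MiSeq -- plus the column summaries. Results are
#' deterministic and invariant to row order.
#'
#' @param tbl A comparison table with columns `reference`, `miseq`, `r9`,
#'   `r94` (proportions) and the three `bias_*` columns, e.g. from
#'   [load_platform_table()].
#' @return List with `correlations` (data frame `pair`, `r`, `p`, `n`) and
#'   the [column_summaries()] result under `summaries`.
#' @export
compare_platforms <- function(tbl) {
  need <- c("reference", "miseq", "r9", "r94")
  if (!all(need %in% names(tbl))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  pairs <- list(
    miseq_vs_reference = c("miseq", "reference"),
    r9_vs_reference = c("r9", "reference"),
    r94_vs_reference = c("r94", "reference"),
    r9_vs_miseq = c("r9", "miseq"),
    r94_vs_miseq = c("r94", "miseq"))
  correlations <- do.call(rbind, lapply(names(pairs), function(nm) {
    pc <- pearson_cor(tbl[[pairs[[nm]][1]]], tbl[[pairs[[nm]][2]]])
    data.frame(pair = nm, r = pc$r, p = pc$p, n = pc$n)
  }))
  list(correlations = correlations, summaries = column_summaries(tbl))
}

#' Write a platform-comparison report as TSV
#'
#' @param report A [compare_platforms()] result.
#' @param path Output path.
#' @return `path`, invisibly. Correlations are printed with r to 2 decimals
#'   and p to 4; summaries keep proportions at 3 decimals and bias at 2.
#' @export
write_comparison_stats <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cors <- report$correlations
  writeLines("pair\tr\tp\tn", con)
  writeLines(sprintf("%s\t%.2f\t%.4f\t%d", cors$pair, cors$r, cors$p, cors$n),
             con)
  writeLines("", con)
  s <- report$summaries$summary
  writeLines(paste(names(s), collapse = "\t"), con)
  fmt_col <- function(col, v) {
    if (grepl("^bias", col)) sprintf("%.2f", v) else sprintf("%.3f", v)
  }
  for (i in seq_len(nrow(s))) {
    cells <- vapply(names(s)[-1], function(col) fmt_col(col, s[[col]][i]),
                    character(1))
    writeLines(paste(c(s$statistic[i], cells), collapse = "\t"), con)
  }
  invisible(path)
}
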