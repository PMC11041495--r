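# Aggregation of risk summaries across splits and trend statistics.

#' Correlation trend between false acceptances and search-space size
#'
#' Pearson correlation between per-split FA counts and the chosen x axis,
#' with the exact small-sample two-tailed t test
#' (`t = r * sqrt(df / (1 - r^2))`, `df = n - 2`).
#'
#' @param summaries a data frame of [count_outcomes()] rows (stacked).
#' @param x_axis `"comparisons"`, `"n_known"` or `"n_unknown"`.
#' @param y column to correlate against the x axis (default `"FA"`).
#' @return a `trend_result`: list with `r`, `n`, `t`, `df`, `p`.
#' @export
fa_trend <- function(summaries, x_axis = c("comparisons", "n_known", "n_unknown"),
                     y = "FA") {
  x_axis <- match.arg(x_axis)
  summaries <- as.data.frame(summaries)
  x <- summaries[[x_axis]]
  fa <- summaries[[y]]
  n <- length(x)
  if (n < 3L) rr_validation_error("a trend needs at least 3 summaries")
  if (length(unique(x)) < 2L) rr_degenerate_error(sprintf("%s is constant; correlation undefined", x_axis))
  if (length(unique(fa)) < 2L) rr_degenerate_error(sprintf("%s is constant; correlation undefined", y))
  xm <- x - mean(x); ym <- fa - mean(fa)
  r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  df <- n - 2L
  t <- if (abs(r) < 1) r * sqrt(df / (1 - r^2)) else sign(r) * Inf
  p <- 2 * pt(-abs(t), df)
  structure(list(r = r, n = n, t = t, df = df, p = p, x_axis = x_axis),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> r = %.3f vs %s (t_%d = %.2f, two-tailed p = %.3g, n = %d)\n",
              x$r, x$x_axis, x$df, x$t, x$p, x$n))
  invisible(x)
}

#' Aggregate risk summaries by configuration
#'
#' One row per group: mean and SD of TA, FA and FAR; the mean of per-run
#' precisions over runs with at least one acceptance (with the count of
#' runs contributing); and the FA/TA ratio of the mean counts. The two
#' precision-style conventions (mean of per-run precisions vs ratio of mean
#' counts) are both reported because they answer different questions and
#' need not agree.
#'
#' @param summaries a data frame of stacked [count_outcomes()] rows.
#' @param by grouping columns (default the split size descriptor).
#' @return a data frame, one row per group, columns `n_runs`, `mean_TA`,
#'   `sd_TA`, `mean_FA`, `sd_FA`, `mean_FAR`, `sd_FAR`, `mean_precision`,
#'   `n_precision`, `fa_ta_of_means`.
#' @export
aggregate_risk <- function(summaries, by = c("n_known", "n_unknown", "n_overlap")) {
  summaries <- as.data.frame(summaries)
  if (nrow(summaries) == 0L) rr_validation_error("no summaries to aggregate")
  missing_by <- setdiff(by, names(summaries))
  if (length(missing_by)) rr_validation_error(sprintf("grouping columns missing: %s",
                                                      paste(missing_by, collapse = ", ")))
  key <- interaction(summaries[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    g <- summaries[key == lv, , drop = FALSE]
    prec <- g$precision[!is.na(g$precision)]
    out <- g[1L, by, drop = FALSE]
    out$n_runs <- nrow(g)
    out$mean_TA <- mean(g$TA); out$sd_TA <- if (nrow(g) > 1L) sd(g$TA) else NA_real_
    out$mean_FA <- mean(g$FA); out$sd_FA <- if (nrow(g) > 1L) sd(g$FA) else NA_real_
    out$mean_FAR <- mean(g$FAR); out$sd_FAR <- if (nrow(g) > 1L) sd(g$FAR) else NA_real_
    out$mean_precision <- if (length(prec)) mean(prec) else NA_real_
    out$n_precision <- length(prec)
    out$fa_ta_of_means <- if (mean(g$TA) > 0) mean(g$FA) / mean(g$TA)
                          else if (mean(g$FA) > 0) Inf else NA_real_
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
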