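#' @title Group comparison and significance tiers
#' @name group-stats
#' @description
#' Per-nucleus metrics are compared between experimental groups with a
#' fixed test assignment: nucleus sizes (approximately normal) use the
#' two-sample t-test, every other metric uses the Kruskal-Wallis rank
#' test (also for two groups). p-values are annotated with the usual
#' tiers: n.s. (p >= 0.05), * (p < 0.05), ** (p < 0.01),
#' *** (p < 0.001). Raw pairwise p-values are reported without
#' multiple-testing correction; a Holm-adjusted column can be requested
#' where many pairs are compared.
NULL

#' Significance tier of a p-value
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector: `"n.s."` for `p >= 0.05`, `"*"` for
#'   `p < 0.05`, `"**"` for `p < 0.01`, `"***"` for `p < 0.001`.
#' @export
significance_tier <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "n.s.")))
}

#' Compare a metric between groups
#'
#' @param values_by_group Named list of numeric vectors, one per group;
#'   each group needs at least 3 values.
#' @param metric_kind `"nucleus_size"` selects the two-sample t-test
#'   (exactly two groups); `"other"` (default) selects the
#'   Kruskal-Wallis rank test, which also handles k > 2 groups.
#' @param var_equal For the t-test: `FALSE` (default) uses the Welch
#'   unequal-variance form, `TRUE` the pooled-variance form.
#' @return Object of class `GroupComparison`: list with `groups`,
#'   `n` (per-group sizes), `test_used`, `statistic`, `p_value`,
#'   `tier` and `note` (non-empty when a degenerate-data convention
#'   was applied).
#' @export
compare_groups <- function(values_by_group,
                           metric_kind = c("other", "nucleus_size"),
                           var_equal = FALSE) {
  metric_kind <- match.arg(metric_kind)
  if (!is.list(values_by_group) || length(values_by_group) < 2 ||
      is.null(names(values_by_group))) {
    stop("`values_by_group` must be a named list of >= 2 groups",
         call. = FALSE)
  }
  sizes <- lengths(values_by_group)
  if (any(sizes < 3)) {
    stop("every group needs at least 3 values", call. = FALSE)
  }
  note <- ""
  if (metric_kind == "nucleus_size") {
    if (length(values_by_group) != 2) {
      stop("the two-sample t-test compares exactly 2 groups", call. = FALSE)
    }
    x <- values_by_group[[1]]; y <- values_by_group[[2]]
    res <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                    error = function(e) NULL)
    if (is.null(res)) {
      # both groups essentially constant: no evidence of a difference
      stat <- 0; p <- 1
      note <- "zero-variance groups; p = 1 by convention"
    } else {
      stat <- unname(res$statistic); p <- res$p.value
    }
    test <- if (var_equal) "two_sample_t" else "welch_t"
  } else {
    pooled <- unlist(values_by_group, use.names = FALSE)
    if (length(unique(pooled)) == 1) {
      stat <- 0; p <- 1
      note <- "all values identical; p = 1 by convention"
    } else {
      g <- factor(rep(names(values_by_group), sizes),
                  levels = names(values_by_group))
      res <- stats::kruskal.test(pooled, g)
      stat <- unname(res$statistic); p <- res$p.value
    }
    test <- "kruskal_wallis"
  }
  structure(list(groups = names(values_by_group), n = unname(sizes),
                 test_used = test, statistic = stat, p_value = p,
                 tier = significance_tier(p), note = note),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("<GroupComparison> ", paste(x$groups, collapse = " vs "), ": ",
      x$test_used, ", p = ", format(x$p_value, digits = 4), " (", x$tier,
      ")\n", sep = "")
  if (nzchar(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Pairwise comparisons of a metric across all group pairs
#'
#' @param df Data frame holding the metric and the group label.
#' @param value_col Name of the numeric metric column.
#' @param group_col Name of the group-label column.
#' @param metric_kind Passed to [compare_groups()].
#' @param holm Add a Holm-adjusted p-value column (default `FALSE`).
#' @return Data frame with one row per unordered group pair: `metric`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `test`, `p_value`, `tier`
#'   (and `p_holm` when requested). Pairs where either group has fewer
#'   than 3 values are skipped.
#' @export
compare_all_pairs <- function(df, value_col, group_col,
                              metric_kind = "other", holm = FALSE) {
  groups <- unique(as.character(df[[group_col]]))
  rows <- list()
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq.int(i + 1, length(groups))) {
        va <- df[[value_col]][df[[group_col]] == groups[i]]
        vb <- df[[value_col]][df[[group_col]] == groups[j]]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        if (length(va) < 3 || length(vb) < 3) next
        cmp <- compare_groups(stats::setNames(list(va, vb),
                                              c(groups[i], groups[j])),
                              metric_kind = metric_kind)
        rows[[length(rows) + 1]] <- data.frame(
          metric = value_col, group_a = groups[i], group_b = groups[j],
          n_a = length(va), n_b = length(vb), test = cmp$test_used,
          p_value = cmp$p_value, tier = cmp$tier)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(0), group_a = character(0),
               group_b = character(0), n_a = integer(0), n_b = integer(0),
               test = character(0), p_value = numeric(0), tier = character(0))
  if (holm && nrow(out)) out$p_holm <- stats::p.adjust(out$p_value, "holm")
  out
}

#' Boxplot summary statistics of a sample
#'
#' Median and quartiles use the linear-interpolation quantile
#' convention (type 7); whiskers are placed at the mean plus/minus two
#' sample standard deviations (n - 1 denominator) and values outside
#' the whisker interval are listed as outliers.
#'
#' @param values Numeric vector with at least 2 values.
#' @return Object of class `BoxplotSummary`: list with `n`, `median`,
#'   `q1`, `q3`, `mean`, `sd`, `whisker_lo`, `whisker_hi`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("at least 2 finite values are required", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(values); s <- stats::sd(values)
  lo <- m - 2 * s; hi <- m + 2 * s
  structure(list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 mean = m, sd = s, whisker_lo = lo, whisker_hi = hi,
                 outliers = values[values < lo | values > hi]),
            class = "BoxplotSummary")
}

#' @export
print.BoxplotSummary <- function(x, ...) {
  cat("<BoxplotSummary> n = ", x$n, ", median ", format(x$median, digits = 4),
      " [Q1 ", format(x$q1, digits = 4), ", Q3 ", format(x$q3, digits = 4),
      "], mean ", format(x$mean, digits = 4), " +/- 2 SD [",
      format(x$whisker_lo, digits = 4), ", ", format(x$whisker_hi, digits = 4),
      "], ", length(x$outliers), " outlier(s)\n", sep = "")
  invisible(x)
}

#' Per-group boxplot summary table
#'
#' @inheritParams compare_all_pairs
#' @return Data frame with one row per group with at least 2 values:
#'   `metric`, `group`, `n`, `median`, `q1`, `q3`, `mean`, `sd`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
boxplot_table <- function(df, value_col, group_col) {
  groups <- unique(as.character(df[[group_col]]))
  rows <- list()
  for (g in groups) {
    v <- df[[value_col]][df[[group_col]] == g]
    v <- v[is.finite(v)]
    if (length(v) < 2) next
    b <- boxplot_summary(v)
    rows[[length(rows) + 1]] <- data.frame(
      metric = value_col, group = g, n = b$n, median = b$median,
      q1 = b$q1, q3 = b$q3, mean = b$mean, sd = b$sd,
      whisker_lo = b$whisker_lo, whisker_hi = b$whisker_hi,
      n_outliers = length(b$outliers))
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(metric = character(0), group = character(0), n = integer(0),
               median = numeric(0), q1 = numeric(0), q3 = numeric(0),
               mean = numeric(0), sd = numeric(0), whisker_lo = numeric(0),
               whisker_hi = numeric(0), n_outliers = integer(0))
}
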