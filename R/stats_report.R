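# Cohort aggregation and the two-sample comparison: per-group mean +/- SD
# and a two-sided Student t test (pooled variance by default, Welch by
# option) at alpha = 0.05.

check_cohort <- function(table, metric) {
  abort_if(!is.data.frame(table) || !all(c("group", metric) %in% names(table)),
           sprintf("`table` must have columns 'group' and '%s'", metric),
           "retinoquant_argument_error")
  invisible(NULL)
}

#' Per-group summary of a cohort metric
#'
#' Sample mean and sample standard deviation (n - 1 denominator) per group,
#' the "mean +/- SD" presentation of cohort endpoints.
#'
#' @param table data.frame with columns `group` and the metric.
#' @param metric name of the metric column.
#' @return data.frame: group, n, mean, sd.
#' @export
summarize_cohort <- function(table, metric) {
  check_cohort(table, metric)
  groups <- sort(unique(as.character(table$group)))
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- table[[metric]][table$group == g]
    abort_if(length(x) < 2L,
             sprintf("group '%s' has fewer than 2 observations", g),
             "retinoquant_argument_error")
    data.frame(group = g, n = length(x), mean = mean(x), sd = sd(x))
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample comparison of a cohort metric
#'
#' Two-sided two-sample t test between exactly two groups: pooled-variance
#' Student t (df = n1 + n2 - 2) by default, Welch by option. Groups are
#' ordered alphabetically; the t statistic is mean(first) - mean(second).
#' Significance is declared at alpha = 0.05.
#'
#' @param table data.frame with columns `group` and the metric.
#' @param metric name of the metric column.
#' @param variant "student" (pooled variance) or "welch".
#' @return a list of class `group_comparison`: metric, groups (the
#'   [summarize_cohort()] table), t_statistic, df, p_value, significant,
#'   variant.
#' @export
compare_groups <- function(table, metric, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  check_cohort(table, metric)
  groups <- sort(unique(as.character(table$group)))
  abort_if(length(groups) != 2L, "exactly two groups are required",
           "retinoquant_argument_error")
  summ <- summarize_cohort(table, metric)
  x <- table[[metric]][table$group == groups[1]]
  y <- table[[metric]][table$group == groups[2]]
  tt <- t.test(x, y, var.equal = (variant == "student"))
  structure(list(metric = metric, groups = summ,
                 t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, significant = tt$p.value < 0.05,
                 variant = variant),
            class = "group_comparison")
}

#' Pooled t test from summary statistics
#'
#' Reconstructs the two-sided pooled-variance Student t test from printed
#' per-group summaries (n, mean, SD) — the form in which cohort endpoints
#' are usually reported.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 per-group summary statistics.
#' @return a list: t_statistic (mean1 - mean2 over the pooled SE), df,
#'   p_value, significant.
#' @export
compare_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  abort_if(n1 < 2 || n2 < 2, "each group needs n >= 2",
           "retinoquant_argument_error")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(t_stat), df)
  list(t_statistic = t_stat, df = df, p_value = p, significant = p < 0.05)
}

#' Write cohort measurements and comparisons to disk
#'
#' Writes `measurements.csv` (the per-image table, verbatim) and
#' `summary.json` (per-group summaries and test results for each
#' comparison). Content is deterministic for fixed input.
#'
#' @param table per-image measurement data.frame.
#' @param comparisons list of `group_comparison` objects (may be empty).
#' @param dir output directory, created if needed.
#' @return the directory, invisibly.
#' @export
write_report <- function(table, comparisons, dir) {
  abort_if(!is.data.frame(table) || nrow(table) == 0L,
           "`table` must be a nonempty data.frame", "retinoquant_argument_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(dir), sprintf("cannot create directory %s", dir),
           "retinoquant_io_error")
  write.csv(table, file.path(dir, "measurements.csv"), row.names = FALSE)
  summ <- lapply(comparisons, function(cmp) {
    list(metric = cmp$metric,
         groups = cmp$groups,
         t_statistic = cmp$t_statistic, df = cmp$df,
         p_value = cmp$p_value, significant = cmp$significant,
         variant = cmp$variant)
  })
  jsonlite::write_json(list(n_images = nrow(table), comparisons = summ),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
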