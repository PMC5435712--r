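#' Per-group mean and SD of a study variable
#'
#' Summaries in mean +/- SD form (sample SD, n - 1 denominator).
#'
#' @param table data.frame with a `group` column (a study table from
#'   [make_study_table()] or read from CSV).
#' @param variable name of a numeric column.
#' @return `data.frame(group, n, mean, sd)`, one row per group.
#' @export
group_summary <- function(table, variable) {
  check_study_variable(table, variable)
  groups <- unique(table$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- table[[variable]][table$group == g]
    if (length(x) < 2L) {
      stop("group '", g, "' has n = ", length(x), "; SD undefined (need n >= 2)")
    }
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x))
  }))
  rownames(out) <- NULL
  out
}

check_study_variable <- function(table, variable) {
  if (!is.data.frame(table) || !"group" %in% names(table)) {
    stop("`table` must be a data.frame with a `group` column")
  }
  if (!variable %in% names(table)) stop("no column '", variable, "' in table")
  if (any(!is.finite(table[[variable]]))) {
    stop("column '", variable, "' contains non-finite values")
  }
  invisible(TRUE)
}

#' Multi-group comparison of a study variable
#'
#' Omnibus test across groups — one-way ANOVA or Kruskal-Wallis — followed
#' (optionally) by two-sided pairwise comparisons with Bonferroni
#' correction (pairwise t tests under `"anova"`, pairwise Wilcoxon
#' rank-sum tests under `"kruskal_wallis"`).
#'
#' @param table data.frame with a `group` column.
#' @param variable name of a numeric column.
#' @param method `"anova"` or `"kruskal_wallis"`.
#' @param pairwise logical; compute the pairwise p-value matrix.
#' @return List with `method`, `statistic` (F or chi-squared), `p_value`,
#'   `df`, `pairwise` (matrix of Bonferroni-adjusted p-values or `NULL`),
#'   `adjust`, and `n` (per-group sizes).
#' @export
compare_groups <- function(table, variable, method = c("anova", "kruskal_wallis"),
                           pairwise = TRUE) {
  method <- match.arg(method)
  check_study_variable(table, variable)
  g <- factor(table$group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  x <- table[[variable]]
  if (stats::var(x) == 0) {
    stop("'", variable, "' is constant across all animals; the ",
         method, " statistic is degenerate (all ties)")
  }
  if (method == "anova") {
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1]]
    statistic <- s[["F value"]][1]
    p_value <- s[["Pr(>F)"]][1]
    df <- s[["Df"]][1:2]
    pw <- if (pairwise) {
      stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni")$p.value
    }
  } else {
    kt <- stats::kruskal.test(x, g)
    statistic <- unname(kt$statistic)
    p_value <- kt$p.value
    df <- unname(kt$parameter)
    pw <- if (pairwise) {
      suppressWarnings(
        stats::pairwise.wilcox.test(x, g, p.adjust.method = "bonferroni",
                                    exact = FALSE)$p.value)
    }
  }
  if (is.na(p_value)) stop("degenerate test: p-value undefined for '", variable, "'")
  list(method = method, statistic = statistic, p_value = p_value, df = df,
       pairwise = if (pairwise) pw else NULL, adjust = "bonferroni",
       n = table(g))
}

#' Pearson correlation and least-squares line between two study variables
#'
#' Pearson r with its two-sided p-value from the t transform on n - 2
#' degrees of freedom, plus the least-squares regression `y ~ x`.
#'
#' @param table data.frame.
#' @param x,y names of numeric columns (metric and remodelling variable).
#' @return List with `r`, `p_value`, `slope`, `intercept`, `n`, `conf_int`
#'   (95% Fisher-z interval for r).
#' @export
correlate <- function(table, x, y) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame")
  for (v in c(x, y)) {
    if (!v %in% names(table)) stop("no column '", v, "' in table")
    if (any(!is.finite(table[[v]]))) stop("column '", v, "' contains non-finite values")
  }
  xv <- table[[x]]; yv <- table[[y]]
  n <- length(xv)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in '", if (stats::sd(xv) == 0) x else y,
         "': correlation undefined")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- stats::lm(yv ~ xv)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = n, conf_int = as.numeric(ct$conf.int))
}

#' Read / write study tables as CSV
#'
#' Fixed header: `id,group,...` with one row per animal.
#'
#' @param table a study data.frame.
#' @param path CSV path.
#' @return `write_study_csv` returns `path` invisibly; `read_study_csv`
#'   the data.frame.
#' @export
write_study_csv <- function(table, path) {
  if (!all(c("id", "group") %in% names(table))) {
    stop("study table needs `id` and `group` columns")
  }
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("id", "group") %in% names(df))) {
    stop("study table CSV needs `id` and `group` columns")
  }
  df
}
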