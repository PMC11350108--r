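#' Group-comparison statistics
#'
#' The non-parametric suite used for cohort comparisons: Wilcoxon rank-sum
#' for two groups (exact enumeration for small samples, normal approximation
#' with tie correction otherwise), Kruskal-Wallis for three or more groups,
#' Pearson/Spearman correlations, an arcsine two-proportion test, and
#' Cohen's h effect size for proportions.
#'
#' @name cohort_stats
NULL

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact when both groups have at most `exact_max` observations and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric samples (each n >= 3)
#' @param exact_max largest per-group n for the exact path
#' @return list with `statistic` (rank-sum W), `p`, `n` (per group),
#'   `method`
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 8) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(a), length(b)),
       method = if (exact) "exact" else "normal approximation")
}

#' Kruskal-Wallis test across three or more groups
#'
#' @param groups list of numeric vectors (>= 3 groups, each n >= 2)
#' @return list with `statistic` (H, tie-corrected), `df`, `p`, `n`
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 3L)
    stop("kruskal_wallis needs >= 3 groups; use wilcoxon_rank_sum for two")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  kw <- stats::kruskal.test(groups)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, n = vapply(groups, length, integer(1)))
}

#' Cohen's h effect size for two proportions
#'
#' `|2 asin(sqrt(p1)) - 2 asin(sqrt(p2))|`.
#'
#' @param p1,p2 proportions in `[0, 1]`
#' @return effect size (non-negative, at most pi)
#' @export
cohens_h <- function(p1, p2) {
  if (any(!is.finite(c(p1, p2))) || any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("proportions must be in [0, 1]")
  abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
}

#' Two-proportion comparison on the arcsine scale with Cohen's h
#'
#' Tests equality of two independent proportions via the arcsine
#' variance-stabilizing transform (z test), reporting Cohen's h alongside.
#'
#' @param x1,x2 successes per group
#' @param n1,n2 group sizes
#' @return list with `statistic` (z), `p`, `h`, `p1`, `p2`
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  h <- cohens_h(p1, p2)
  z <- (2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))) / sqrt(1 / n1 + 1 / n2)
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)), h = h, p1 = p1, p2 = p2)
}

#' Correlation with p-value
#'
#' @param x,y numeric vectors (n >= 4)
#' @param method `"pearson"` or `"spearman"`
#' @return list with `estimate`, `p`, `n`, `method`
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("correlations needs n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Pairwise group comparisons of cohort measures
#'
#' Runs [wilcoxon_rank_sum()] for every measure between two groups of a
#' feature table and assembles the comparison report.
#'
#' @param table data.frame with a `group` column and measure columns
#' @param group_a,group_b group labels to compare
#' @param measures measure column names (default: all numeric columns)
#' @return data.frame: `measure`, `group_a`, `group_b`, `median_a`,
#'   `median_b`, `statistic`, `p`
#' @export
compare_groups <- function(table, group_a, group_b, measures = NULL) {
  if (is.null(measures))
    measures <- names(table)[vapply(table, is.numeric, logical(1)) &
                               !names(table) %in% c("subject")]
  ia <- table$group == group_a; ib <- table$group == group_b
  rows <- lapply(measures, function(m) {
    w <- wilcoxon_rank_sum(table[[m]][ia], table[[m]][ib])
    data.frame(measure = m, group_a = group_a, group_b = group_b,
               median_a = stats::median(table[[m]][ia]),
               median_b = stats::median(table[[m]][ib]),
               statistic = w$statistic, p = w$p)
  })
  do.call(rbind, rows)
}
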