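# Descriptive and follow-up statistics: Welch's t (from vectors or summary
# statistics), chi-squared independence tests with the 2x2 continuity
# convention, and two-tailed Spearman correlation.

#' Welch's two-sample t test
#'
#' Unequal-variance t test, either from two raw vectors or directly from
#' summary statistics (mean, SD, n per group) as printed in a demographics
#' table. `t = (m2 - m1) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p.
#'
#' @param x,y raw vectors, or NULL when summary statistics are supplied.
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics (used when `x` is
#'   NULL).
#' @return list: `statistic`, `df`, `p`, `method`.
#' @export
welch_t <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL, n1 = NULL,
                    mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 <= 0 && sd2 <= 0) stop("zero variance in both groups")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
       method = "Welch two-sample t")
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared on an r x c count table with expected counts
#' `E = row * col / N`. The Yates 0.5 continuity correction is applied only
#' to 2x2 tables (and only when `yates = TRUE`, the default there); larger
#' tables are never corrected — the convention under which the printed
#' demographic comparisons of a 2x2 sex table (corrected) and 2x3 smoking
#' tables (uncorrected) are reproduced from their counts.
#'
#' @param table numeric matrix of nonnegative counts.
#' @param yates apply continuity correction if the table is 2x2 (default
#'   TRUE).
#' @return list: `statistic`, `df`, `p`, `method`, `correction`.
#' @export
chisq_independence <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in the table")
  E <- outer(rs, cs) / sum(table)
  corr <- yates && all(dim(table) == c(2, 2))
  adj <- if (corr) pmin(abs(table - E), 0.5) else 0  # never overshoot
  stat <- sum((abs(table - E) - adj)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       method = "Pearson chi-squared", correction = corr)
}

#' Two-tailed Spearman rank correlation
#'
#' `rho` is the Pearson correlation of average ranks (ties share their mean
#' rank); the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `rho`, `statistic` (the t value), `df`, `p`, `method`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector has no rank correlation")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0; t <- sign(rho) * Inf
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, statistic = t, df = n - 2, p = p,
       method = "Spearman rank correlation (t approximation)")
}

#' Table-1-style demographics comparison
#'
#' Given a phenotype table and an exposure column, runs Welch's t on the
#' continuous variables and chi-squared tests on the categorical ones,
#' mirroring the descriptive comparison of exposed vs unexposed groups.
#'
#' @param phenotypes data.frame with the exposure column plus any of `age`,
#'   `sex`, `smoking` (categorical), `lifetime_MDD`.
#' @param exposure_col name of the 0/1 exposure column (default
#'   `"exposure"`).
#' @return data.frame: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
describe_cohort <- function(phenotypes, exposure_col = "exposure") {
  e <- phenotypes[[exposure_col]]
  rows <- list()
  add <- function(variable, test, r)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = r$statistic,
      df = r$df, p = r$p, stringsAsFactors = FALSE)
  for (v in intersect(c("age", "BMI", "smoking_proxy_M"), names(phenotypes)))
    add(v, "welch-t",
        welch_t(phenotypes[[v]][e == 0], phenotypes[[v]][e == 1]))
  for (v in intersect(c("sex", "smoking", "lifetime_MDD", "batch"),
                      names(phenotypes)))
    add(v, "chi-squared",
        chisq_independence(table(e, phenotypes[[v]])))
  do.call(rbind, rows)
}
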