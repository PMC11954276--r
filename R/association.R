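#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates (with intercept); the p-value uses
#' `t = r sqrt((n - 2 - k) / (1 - r^2))` with k covariates, two-sided.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data.frame (k columns).
#' @return List with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates) {
  Z <- cbind(1, as.matrix(covariates))
  k <- ncol(Z) - 1L
  n <- length(x)
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  rx <- x - Z %*% qr.solve(Z, x)
  ry <- y - Z %*% qr.solve(Z, y)
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300))
    stop("zero residual variance after removing covariates")
  r <- stats::cor(rx, ry)[1L]
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Bonferroni adjustment
#'
#' `min(1, p * n_tests)`.
#'
#' @param p_raw Raw p-value(s).
#' @param n_tests Number of tests in the family (default 7).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p_raw, n_tests = 7L) pmin(1, p_raw * n_tests)

#' Two-group comparison with automatic test choice
#'
#' Categorical variables (factor/character/logical) get a chi-square test on
#' the contingency table (no continuity correction). Quantitative variables
#' are gated by per-group Shapiro-Wilk normality at alpha 0.05: both normal
#' uses a pooled-variance two-sample t test, otherwise Mann-Whitney U. All
#' tests two-sided.
#'
#' @param values Vector of observations.
#' @param groups Two-level grouping vector.
#' @return List with `statistic`, `p`, `test`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly 2 groups")
  if (is.character(values) || is.factor(values) || is.logical(values)) {
    tst <- stats::chisq.test(table(values, groups), correct = FALSE)
    return(list(statistic = unname(tst$statistic), p = tst$p.value,
                test = "chi-square"))
  }
  g1 <- values[groups == levels(groups)[1L]]
  g2 <- values[groups == levels(groups)[2L]]
  normal <- function(v) {
    if (length(unique(v)) < 3L) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }
  if (normal(g1) && normal(g2)) {
    tst <- stats::t.test(g1, g2, var.equal = TRUE)
    list(statistic = unname(tst$statistic), p = tst$p.value, test = "t")
  } else {
    tst <- stats::wilcox.test(g1, g2, exact = NULL)
    list(statistic = unname(tst$statistic), p = tst$p.value,
         test = "mann-whitney")
  }
}

#' Age-adjusted feature-scale associations within each group
#'
#' For every (selected feature, clinical scale) pair within each diagnostic
#' group, computes the partial correlation controlling for the covariate
#' (age by default) and applies Bonferroni correction with `n_tests` tests
#' per family.
#'
#' @param features Numeric matrix of selected features (subjects x features).
#' @param clinical Clinical data.frame including `group` and the covariate.
#' @param scales Clinical scale column names.
#' @param covariate Covariate column (default `"age"`).
#' @param n_tests Bonferroni family size (default 7).
#' @return data.frame of association results (one row per feature-scale-
#'   group triple).
#' @export
associate_features <- function(features, clinical,
                               scales = c("moca", "updrs3", "nmss", "pdq39",
                                          "hama", "hamd", "bmi"),
                               covariate = "age", n_tests = 7L) {
  n_tests <- as.integer(n_tests)
  features <- as.matrix(features)
  out <- list()
  for (g in unique(clinical$group)) {
    rows <- clinical$group == g
    for (f in colnames(features)) for (s in scales) {
      pc <- tryCatch(
        partial_correlation(features[rows, f], clinical[rows, s],
                            clinical[rows, covariate]),
        error = function(e) NULL)
      if (is.null(pc)) next
      out[[length(out) + 1L]] <- data.frame(
        feature = f, scale = s, group = g,
        r_partial = pc$r, p_raw = pc$p,
        p_bonferroni = bonferroni(pc$p, n_tests),
        n_tests = n_tests,
        significant = bonferroni(pc$p, n_tests) < 0.05,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
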