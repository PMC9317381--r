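#' Mann-Whitney U test
#'
#' U statistic of the first group with midrank tie handling. The
#' two-sided p-value uses the exact null distribution when the samples
#' are small (`n1 * n2 <= 400`) and tie-free, and otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return list with `U` (for the first group) and `p.value`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 == 0) return(list(U = U, p.value = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p.value = p)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Pearson's statistic with optional Yates continuity correction
#' (|O - E| reduced by min(0.5, |O - E|)); p-value from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative integer counts with no zero
#'   row or column margin.
#' @param yates apply the continuity correction (default `FALSE`).
#' @return list with `statistic` and `p.value`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  dev <- abs(table - E)
  if (yates) dev <- dev - pmin(0.5, dev)
  stat <- sum(dev^2 / E)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cohen's d between two groups
#'
#' Standardized mean difference `(mean(y) - mean(x)) / s_pooled` with the
#' bias-corrected pooled variance. The sign convention is positive when
#' values are larger in the second group (cluster 1).
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return numeric effect size.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance")
  (mean(y) - mean(x)) / sqrt(sp2)
}

#' Nonparametric comparison of two detected subgroups
#'
#' Runs Mann-Whitney U tests with Cohen's d effect sizes for every
#' numeric variable (olfaction variables plus age and BMI), a chi-square
#' test for the sex contingency, and optionally one for a second
#' categorical variable such as the olfactory diagnosis. P-values are
#' tiered at the nominal 0.05 level and at the Bonferroni-corrected
#' threshold `alpha / n_tests`.
#'
#' @param table a [cohort_table()] (preprocessed or raw).
#' @param labels two-group membership vector (e.g. 0/1 cluster labels).
#' @param categorical optional named list of extra binary vectors to
#'   cross-tabulate against the groups (e.g.
#'   `list(diagnosis = ...)`).
#' @param alpha familywise significance level (default 0.05).
#' @param n_tests number of tests the Bonferroni correction divides
#'   alpha by; defaults to the number of numeric variables plus the
#'   number of contingency tests (18 for the full battery).
#' @param yates Yates correction for the contingency tests (default
#'   `TRUE`, appropriate for observed cross-tabulations).
#' @return object of class `comparison_report`: `variables` data.frame
#'   (variable, U, p, d, tier), `categorical` data.frame (variable,
#'   statistic, p, tier), `alpha`, `n_tests`.
#' @export
compare_groups <- function(table, labels, categorical = list(),
                           alpha = 0.05, n_tests = NULL, yates = TRUE) {
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required")
  num_vars <- c(olfaction_vars(table),
                intersect(c("age", "bmi"), covariate_vars(table)))
  has_sex <- "sex" %in% covariate_vars(table)
  if (is.null(n_tests))
    n_tests <- length(num_vars) + has_sex + length(categorical)
  bonf <- alpha / n_tests
  tier <- function(p) ifelse(p < bonf, "bonferroni",
                             ifelse(p < alpha, "nominal", "ns"))
  rows <- lapply(num_vars, function(v) {
    x <- table$values[labels == groups[1], v]
    y <- table$values[labels == groups[2], v]
    mw <- mann_whitney_u(x, y)
    data.frame(variable = v, U = mw$U, p = mw$p.value,
               d = cohens_d(x, y), tier = tier(mw$p.value))
  })
  variables <- do.call(rbind, rows)

  cats <- list()
  if (has_sex)
    cats$sex <- table$values[, "sex"]
  cats <- c(cats, categorical)
  cat_rows <- lapply(names(cats), function(v) {
    tab <- base::table(factor(labels), factor(cats[[v]]))
    cs <- chi_square_2x2(tab, yates = yates)
    data.frame(variable = v, statistic = cs$statistic, p = cs$p.value,
               tier = tier(cs$p.value))
  })
  categorical_df <- if (length(cat_rows)) do.call(rbind, cat_rows)
  else data.frame(variable = character(), statistic = numeric(),
                  p = numeric(), tier = character())
  structure(list(variables = variables, categorical = categorical_df,
                 alpha = alpha, n_tests = n_tests, yates = yates),
            class = "comparison_report")
}
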