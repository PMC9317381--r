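#' D'Agostino-Pearson omnibus normality test
#'
#' Combines D'Agostino's skewness z-test with the Anscombe-Glynn kurtosis
#' z-test into the omnibus statistic K^2 = z_skew^2 + z_kurt^2, referred
#' to a chi-square distribution with 2 degrees of freedom. Both component
#' tests use the standard normalizing transformations of the sample
#' skewness g1 = m3 / m2^(3/2) and kurtosis b2 = m4 / m2^2 (central
#' moments with divisor n).
#'
#' @param values numeric vector; at least 20 non-missing values (the
#'   kurtosis approximation is unreliable below that).
#' @return list with `statistic` (K^2), `p.value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 20) stop("at least 20 non-missing values required")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- .Machine$double.eps
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (1 - 2 / (9 * A) - term2) / sqrt(2 / (9 * A))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2,
       p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

tukey_ladder_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2)

#' Apply a Tukey ladder-of-powers transform
#'
#' Power 0 is the logarithm; negative powers are negated (`-x^p`) so every
#' rung is monotone increasing on the (offset-shifted) data.
#'
#' @param x numeric vector.
#' @param power one of -2, -1, -1/2, 0, 1/2, 1, 2.
#' @param offset value added before transforming; used when nonpositive
#'   values would make the rung undefined.
#' @return transformed numeric vector (NA preserved).
#' @export
tukey_transform <- function(x, power, offset = 0) {
  if (!power %in% tukey_ladder_powers()) stop("power not on the ladder")
  xs <- x + offset
  if (power != 1 && any(xs <= 0, na.rm = TRUE))
    stop("nonpositive values after offset for power ", power)
  if (power == 0) log(xs)
  else if (power < 0) -(xs^power)
  else xs^power
}

#' Select the normality-maximizing Tukey ladder transform
#'
#' Tries every rung of the canonical ladder \{-2, -1, -1/2, 0, 1/2, 1, 2\}
#' (0 = log, negative powers negated to stay monotone) and returns the one
#' whose transformed values maximize the D'Agostino-Pearson p-value. When
#' the raw data contain nonpositive values, an offset of `1 - min(x)` is
#' applied for every rung except the identity, so each rung stays
#' monotone increasing. Ties are broken toward
#' power 1 (no transform), then toward the smaller absolute power.
#'
#' @param values numeric vector with at least 20 non-missing entries.
#' @return list with `power`, `offset`, `p.value` and `transformed`
#'   (same length as the input, NA preserved).
#' @export
select_tukey_transform <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 20) stop("at least 20 non-missing values required")
  if (stats::sd(obs) == 0) stop("constant input")
  minx <- min(obs)
  cand <- lapply(tukey_ladder_powers(), function(p) {
    offset <- if (p != 1 && minx <= 0) 1 - minx else 0
    tx <- tukey_transform(values, p, offset)
    pv <- tryCatch(dagostino_pearson(tx)$p.value, error = function(e) -Inf)
    list(power = p, offset = offset, p.value = pv, transformed = tx)
  })
  pvals <- vapply(cand, `[[`, numeric(1), "p.value")
  # tie preference: power 1 first, then smaller |power|, positive before
  # negative at equal magnitude
  pref <- order(vapply(cand, function(cc) cc$power != 1, logical(1)),
                abs(tukey_ladder_powers()), -tukey_ladder_powers())
  best <- pref[which.max(pvals[pref])]
  cand[[best]]
}

#' Drop variables and cases exceeding a missingness cutoff
#'
#' Variables with a missing fraction at or above the cutoff are dropped
#' first; then cases with a missing fraction at or above the cutoff over
#' the retained variables are dropped. Retained cells are unchanged.
#'
#' @param table a [cohort_table()].
#' @param cutoff missing-fraction cutoff in (0, 1]; default 0.20, the
#'   retention rule "less than 20% missing".
#' @return filtered [cohort_table()].
#' @export
filter_missingness <- function(table, cutoff = 0.20) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  vals <- table$values
  var_frac <- colMeans(is.na(vals))
  keep_var <- var_frac < cutoff
  if (!any(keep_var)) stop("all variables exceed the missingness cutoff")
  vals <- vals[, keep_var, drop = FALSE]
  case_frac <- rowMeans(is.na(vals))
  keep_case <- case_frac < cutoff
  cohort_table(vals[keep_case, , drop = FALSE],
               table$roles[colnames(vals)],
               table$subject_ids[keep_case],
               table$transforms[intersect(names(table$transforms),
                                          colnames(vals))])
}

#' Impute missing olfaction cells by chained random forests
#'
#' Multiple-imputation-by-chained-equations style single imputation:
#' missing cells are initialized at the column median of the observed
#' values, then each olfaction variable with missing cells is regressed in
#' turn on all other variables with a random forest and its missing cells
#' replaced by the forest predictions, cycling for `n_iter` iterations.
#' Only olfaction variables are imputation targets; covariates may serve
#' as predictors. Observed cells are untouched and forest regression
#' predictions are convex combinations of observed responses, hence stay
#' within the observed range.
#'
#' @param table a [cohort_table()]; every variable must have < 20%
#'   missing and at least one observed value.
#' @param seed integer seed; identical seeds give identical imputations.
#' @param n_iter chained iterations (default 5).
#' @param num_trees forest size per fit (default 100).
#' @return completed [cohort_table()].
#' @export
impute_chained_rf <- function(table, seed = 1L, n_iter = 5, num_trees = 100) {
  vals <- table$values
  if (!anyNA(vals)) return(table)
  if (any(colMeans(is.na(vals)) >= 0.2))
    stop("a variable has >= 20% missing; run filter_missingness() first")
  if (any(colSums(!is.na(vals)) == 0))
    stop("a variable has no observed values")
  targets <- intersect(olfaction_vars(table),
                       colnames(vals)[colSums(is.na(vals)) > 0])
  miss <- is.na(vals)
  filled <- vals
  for (j in seq_len(ncol(filled)))
    filled[miss[, j], j] <- stats::median(vals[, j], na.rm = TRUE)
  set.seed(seed)
  for (iter in seq_len(n_iter)) {
    for (v in targets) {
      obs <- !miss[, v]
      df <- as.data.frame(filled)
      fit <- ranger::ranger(
        x = df[obs, setdiff(colnames(filled), v), drop = FALSE],
        y = filled[obs, v],
        num.trees = num_trees, num.threads = 1,
        seed = seed + 1000L * iter + match(v, targets))
      pred <- stats::predict(
        fit, df[miss[, v], setdiff(colnames(filled), v), drop = FALSE])
      filled[miss[, v], v] <- pred$predictions
    }
  }
  out <- table
  out$values <- filled
  out
}

#' Z-standardize the olfaction variables of a cohort table
#'
#' Centers and scales each olfaction column to mean 0 and sample standard
#' deviation 1 (denominator n - 1). Covariate columns are left untouched.
#'
#' @param table a complete [cohort_table()].
#' @return standardized [cohort_table()].
#' @export
z_standardize <- function(table) {
  vals <- table$values
  ov <- olfaction_vars(table)
  if (anyNA(vals[, ov])) stop("olfaction columns must be complete")
  sds <- apply(vals[, ov, drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column: ", paste(ov[sds == 0], collapse = ", "))
  vals[, ov] <- scale(vals[, ov, drop = FALSE])
  out <- table
  out$values <- vals
  out
}

#' Distribution-aware preprocessing of a cohort table
#'
#' Applies, in order: per-variable Tukey ladder transform selection (for
#' olfaction variables and BMI; age and the binary sex indicator are left
#' on their original scale), the 20% missingness retention rule, and
#' chained random-forest imputation of the olfaction variables. The chosen
#' transforms are recorded in the returned table's metadata.
#'
#' @param table a raw [cohort_table()].
#' @param seed integer seed for the imputation forests.
#' @param cutoff missingness retention cutoff (default 0.20).
#' @return preprocessed, complete [cohort_table()].
#' @export
preprocess_cohort <- function(table, seed = 1L, cutoff = 0.20) {
  vars <- c(olfaction_vars(table), intersect("bmi", covariate_vars(table)))
  for (v in vars) {
    sel <- select_tukey_transform(table$values[, v])
    table$values[, v] <- sel$transformed
    table$transforms[[v]] <- list(power = sel$power, offset = sel$offset)
  }
  table <- filter_missingness(table, cutoff)
  impute_chained_rf(table, seed = seed)
}
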