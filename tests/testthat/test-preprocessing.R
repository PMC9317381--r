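test_that("D'Agostino-Pearson omnibus matches frozen reference values", {
  # reference statistics computed once with an independent implementation
  # of the same K^2 omnibus (skewness + kurtosis z-tests)
  r1 <- dagostino_pearson((1:25)^1.5)
  expect_equal(r1$statistic, 3.928202862830309, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.14028188289217972, tolerance = 1e-10)
  expect_equal(r1$z_skew, 0.832488666729925, tolerance = 1e-10)
  expect_equal(r1$z_kurt, -1.7986565771699001, tolerance = 1e-10)
  # exactly symmetric data: the skewness component vanishes
  expect_lt(abs(dagostino_pearson(1:25)$z_skew), 1e-6)
  r2 <- dagostino_pearson(exp(seq(0, 3, length.out = 30)))
  expect_equal(r2$statistic, 5.791006144197225, tolerance = 1e-10)
  expect_equal(r2$z_skew, 2.375077583802006, tolerance = 1e-10)
  expect_equal(r2$z_kurt, 0.3873146203262283, tolerance = 1e-10)
  x3 <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.2, 6.1, 0.5, 3.9, 4.0, 2.8,
          3.1, 5.0, 1.9, 2.5, 3.6, 4.8, 2.0, 3.0, 4.1)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$statistic, 0.038261770541983445, tolerance = 1e-10)
  expect_equal(r3$p.value, 0.9810509487199901, tolerance = 1e-10)
})

test_that("normality test is calibrated on normal and powerful on lognormal data", {
  pn <- vapply(1:100, function(s) {
    set.seed(s); dagostino_pearson(stats::rnorm(1000))$p.value
  }, numeric(1))
  expect_gte(sum(pn > 0.01), 98)
  pl <- vapply(1:20, function(s) {
    set.seed(s); dagostino_pearson(stats::rlnorm(1000))$p.value
  }, numeric(1))
  expect_true(all(pl < 0.001))
  expect_error(dagostino_pearson(rep(1, 30)), "variance")
  expect_error(dagostino_pearson(stats::rnorm(10)), "at least 20")
})

test_that("ladder selection finds log for lognormal and identity for normal data", {
  hits_log <- vapply(1:100, function(s) {
    set.seed(s)
    select_tukey_transform(stats::rlnorm(1000))$power == 0
  }, logical(1))
  expect_gte(sum(hits_log), 95)
  hits_id <- vapply(1:100, function(s) {
    set.seed(s)
    select_tukey_transform(stats::rnorm(1000, mean = 10))$power == 1
  }, logical(1))
  expect_gt(sum(hits_id), 50)
  # right-skewed data get a power below 1
  powers <- vapply(1:20, function(s) {
    set.seed(s)
    select_tukey_transform(abs(stats::rnorm(500))^2)$power
  }, numeric(1))
  expect_true(all(powers < 1))
  expect_error(select_tukey_transform(rep(3, 50)), "constant")
})

test_that("a reciprocal-square-root-shaped skew selects a negative power", {
  # x = u^-2 with u normal and positive: -x^(-1/2) recovers normality
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    u <- stats::rnorm(500, mean = 5, sd = 0.5)
    select_tukey_transform(u^-2)$power
  }, numeric(1))
  expect_true(stats::median(hits) < 0)
})

test_that("ladder transforms are monotone and handle nonpositive values", {
  set.seed(1)
  x <- stats::rnorm(100)
  for (p in c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
    offset <- if (p != 1) 1 - min(x) else 0
    tx <- tukey_transform(x, p, offset)
    expect_equal(order(tx), order(x))
  }
  expect_error(tukey_transform(c(-1, 0, 1), 0), "nonpositive")
})

test_that("missingness filter drops at the 20% threshold, variables first", {
  set.seed(2)
  vals <- matrix(stats::rnorm(135 * 3), 135, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  vals[1:28, "a"] <- NA  # 20.7% -> dropped
  vals[1:26, "b"] <- NA  # 19.3% -> retained
  tab <- cohort_table(vals, c(a = "olfaction", b = "olfaction",
                              c = "olfaction"))
  filt <- filter_missingness(tab)
  expect_setequal(colnames(filt$values), c("b", "c"))
  # complete table is untouched
  tab2 <- cohort_table(matrix(stats::rnorm(40), 10, 4,
                              dimnames = list(NULL, letters[1:4])),
                       stats::setNames(rep("olfaction", 4), letters[1:4]))
  expect_identical(filter_missingness(tab2)$values, tab2$values)
  # cases above the cutoff over retained variables are dropped
  vals3 <- matrix(stats::rnorm(50), 10, 5,
                  dimnames = list(NULL, letters[1:5]))
  vals3[1, 1:2] <- NA  # 40% missing in row 1
  tab3 <- cohort_table(vals3, stats::setNames(rep("olfaction", 5),
                                              letters[1:5]))
  expect_equal(nrow(filter_missingness(tab3)$values), 9)
})

test_that("chained-RF imputation preserves observed cells and stays in range", {
  gen <- generate_cohort(synthetic_config(seed = 4))
  tab <- gen$table
  obs_mask <- !is.na(tab$values)
  imp <- impute_chained_rf(tab, seed = 11)
  expect_false(anyNA(imp$values[, olfaction_vars(imp)]))
  expect_identical(imp$values[obs_mask], tab$values[obs_mask])
  for (v in olfaction_vars(tab)) {
    miss <- is.na(tab$values[, v])
    if (!any(miss)) next
    rng <- range(tab$values[!miss, v])
    expect_true(all(imp$values[miss, v] >= rng[1] &
                      imp$values[miss, v] <= rng[2]))
  }
  # determinism and no-op on complete data
  imp2 <- impute_chained_rf(tab, seed = 11)
  expect_identical(imp$values, imp2$values)
  expect_identical(impute_chained_rf(imp, seed = 1)$values, imp$values)
})

test_that("chained-RF imputation beats column-mean imputation on correlated data", {
  set.seed(21)
  n <- 200
  z <- stats::rnorm(n)
  vals <- cbind(a = z + 0.3 * stats::rnorm(n),
                b = z + 0.3 * stats::rnorm(n),
                c = z + 0.3 * stats::rnorm(n),
                d = stats::rnorm(n))
  truth <- vals
  mask <- matrix(FALSE, n, 4)
  mask[sample(n * 3, 30)] <- TRUE  # MCAR on the correlated columns
  vals[mask] <- NA
  tab <- cohort_table(vals, stats::setNames(rep("olfaction", 4),
                                            colnames(vals)))
  imp <- impute_chained_rf(tab, seed = 5)
  rmse_rf <- sqrt(mean((imp$values[mask] - truth[mask])^2))
  means <- colMeans(vals, na.rm = TRUE)
  mean_filled <- vals
  for (j in 1:4) mean_filled[mask[, j], j] <- means[j]
  rmse_mean <- sqrt(mean((mean_filled[mask] - truth[mask])^2))
  expect_lte(rmse_rf, rmse_mean)
})

test_that("z-standardization gives mean 0, sample SD 1 on olfaction columns", {
  sc <- small_cohort(seed = 2)
  Z <- olfaction_matrix(sc$ztab)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_true(all(abs(apply(Z, 2, stats::sd) - 1) < 1e-12))
  # idempotent up to floating point
  expect_equal(z_standardize(sc$ztab)$values, sc$ztab$values,
               tolerance = 1e-12)
  bad <- cohort_table(cbind(a = rep(1, 30), b = stats::rnorm(30)),
                      c(a = "olfaction", b = "olfaction"))
  expect_error(z_standardize(bad), "zero-variance")
})

test_that("pipeline preprocessing contracts skewed thresholds and distances", {
  # lognormal marginals at n = 135 make the log rung and its ladder
  # neighbours nearly equivalent, so assert the selection distribution
  powers <- sapply(1:10, function(s) {
    gen <- generate_cohort(synthetic_config(seed = s, missing_fraction = 0))
    vapply(c("olf_threshold", "distance_right", "distance_left"),
           function(v) select_tukey_transform(gen$table$values[, v])$power,
           numeric(1))
  })
  # a contractive rung (power < 1) is chosen nearly always, and the log
  # rung is the modal choice for the strongly skewed distances
  expect_gte(mean(powers < 1), 0.9)
  dist_powers <- powers[c("distance_right", "distance_left"), ]
  expect_gte(mean(dist_powers == 0), 0.5)

  sc <- small_cohort(seed = 6)
  tr <- sc$pre$transforms
  # transform metadata recorded for every olfaction variable and BMI
  expect_true(all(c(olfaction_vars(sc$pre), "bmi") %in% names(tr)))
  # monotone: subject rank order preserved within each transformed variable
  raw <- generate_cohort(synthetic_config(seed = 6))$table
  v <- "distance_right"
  obs <- !is.na(raw$values[, v])
  common <- intersect(sc$pre$subject_ids, raw$subject_ids[obs])
  expect_equal(order(sc$pre$values[match(common, sc$pre$subject_ids), v]),
               order(raw$values[match(common, raw$subject_ids), v]))
})
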