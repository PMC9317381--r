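test_that("stratified holdout puts aside 20% of each cluster", {
  labels <- rep(c(0, 1), c(80, 55))
  split <- holdout_split(labels, seed = 1)
  expect_equal(sum(labels[split$validation] == 0), 16)
  expect_equal(sum(labels[split$validation] == 1), 11)
  expect_length(intersect(split$train, split$validation), 0)
  split2 <- holdout_split(labels, seed = 1)
  expect_identical(split, split2)
  expect_false(identical(split, holdout_split(labels, seed = 2)))
  expect_error(holdout_split(labels, fraction = 0), "between 0 and 1")
  expect_error(holdout_split(rep(c(0, 1), c(80, 3))), "too small")
})

test_that("a perfectly predictive variable is always selected", {
  set.seed(5)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(oracle = y + 0.05 * stats::rnorm(n),
             matrix(stats::rnorm(n * 7), n, 7))
  colnames(X)[2:8] <- paste0("noise", 1:7)
  scheme <- cv_scheme(5, 2, seed = 3)
  for (alg in c("svm", "logreg")) {
    cnt <- run_selection_method("SKB", alg, X, y, default_tuned()[[alg]],
                                scheme)
    expect_equal(unname(cnt["oracle"]), scheme$n_runs)
  }
  cnt_sfm <- run_selection_method("SFM", "rf", X, y, default_tuned()$rf,
                                  scheme)
  expect_equal(unname(cnt_sfm["oracle"]), scheme$n_runs)
})

test_that("forward SFS finds both informative variables on separable data", {
  set.seed(6)
  n <- 120
  # the class is separable only by the sum of the two informative
  # variables, so a greedy search must pick up both
  inf1 <- stats::rnorm(n)
  inf2 <- stats::rnorm(n)
  y <- as.integer(inf1 + inf2 > 0)
  X <- cbind(inf1 = inf1, inf2 = inf2, matrix(stats::rnorm(n * 6), n, 6))
  colnames(X)[3:8] <- paste0("noise", 1:6)
  scheme <- cv_scheme(5, 2, seed = 4)
  cnt <- run_selection_method("SFSf", "svm", X, y, default_tuned()$svm,
                              scheme)
  expect_gte(min(cnt[c("inf1", "inf2")]), round(0.9 * scheme$n_runs))
  expect_true(all(cnt <= scheme$n_runs))
})

test_that("RFE keeps the top half and backward SFS returns a valid subset", {
  set.seed(7)
  n <- 90
  y <- rep(0:1, each = n / 2)
  X <- cbind(good = 2 * y + stats::rnorm(n),
             matrix(stats::rnorm(n * 5), n, 5))
  colnames(X)[2:6] <- paste0("noise", 1:5)
  scheme <- cv_scheme(5, 1, seed = 5)
  cnt_rfe <- run_selection_method("RFE", "logreg", X, y,
                                  default_tuned()$logreg, scheme)
  expect_equal(unname(cnt_rfe["good"]), scheme$n_runs)
  cnt_b <- run_selection_method("SFSb", "logreg", X, y,
                                default_tuned()$logreg, scheme)
  expect_true(all(cnt_b >= 0 & cnt_b <= scheme$n_runs))
})

test_that("per-method ABC consolidation isolates dominant counts", {
  counts <- c(a = 100, b = 98, c = 3, d = 2, e = 1, f = 1, g = 0, h = 0)
  expect_setequal(consolidate_method(counts), c("a", "b"))
  dvec <- c(v1 = 2.5, v2 = 0.2, v3 = 0.15, v4 = 0.1, v5 = 0.1)
  expect_equal(consolidate_method(dvec), "v1")
  # uniform counts stay legal (no crash, contiguous result)
  expect_no_error(consolidate_method(c(x = 5, y = 5, z = 5, w = 5)))
  expect_error(consolidate_method(c(a = 0, b = 0, c = 0)), "all-zero")
})

test_that("the ensemble is structurally sound and deterministic", {
  sc <- small_cohort(seed = 9)
  m <- pca_project(olfaction_matrix(sc$ztab))
  sol <- kmeans_cluster(m$scores[, 1:m$n_retained, drop = FALSE], 2,
                        seed = 9)
  X <- olfclust:::feature_matrix(sc$ztab)
  y <- factor(sol$labels)
  split <- holdout_split(sol$labels, seed = 9)
  selmat <- feature_selection_ensemble(
    X[split$train, ], y[split$train], olfaction = olfaction_vars(sc$ztab),
    tuned = default_tuned(), scheme = cv_scheme(5, 1, seed = 10))
  expect_length(selmat$methods, 17)
  expect_equal(dim(selmat$a_membership), c(17L, ncol(X)))
  expect_true(all(selmat$sum_score >= 0 & selmat$sum_score <= 17))
  # PCA row cannot select covariates (structural zeros)
  expect_false(any(selmat$a_membership["PCA", c("age", "sex", "bmi")]))
  # counts rows bounded by the number of runs; NA for the two
  # non-counting methods
  expect_true(all(is.na(selmat$counts["PCA", ])))
  expect_true(all(is.na(selmat$counts["CohensD", ])))
  expect_true(all(selmat$counts[-(1:2), ] <= selmat$scheme$n_runs))
  # consolidation reproduces the stored summary
  cons <- ensemble_consolidate(selmat)
  expect_identical(cons$sum_score, selmat$sum_score)
  expect_identical(cons$final_set, selmat$final_set)
  # determinism: a second identical run gives the identical matrix
  selmat2 <- feature_selection_ensemble(
    X[split$train, ], y[split$train], olfaction = olfaction_vars(sc$ztab),
    tuned = default_tuned(), scheme = cv_scheme(5, 1, seed = 10))
  expect_identical(selmat$a_membership, selmat2$a_membership)
  expect_identical(selmat$counts, selmat2$counts)
})

test_that("target contrast is a signed difference with antisymmetry", {
  a <- c(v1 = 10, v2 = 4, v3 = 0)
  b <- c(v3 = 2, v1 = 3, v2 = 4)
  expect_equal(target_contrast(a, a), c(v1 = 0, v2 = 0, v3 = 0))
  expect_equal(target_contrast(a, b), c(v1 = 7, v2 = 0, v3 = -2))
  expect_equal(target_contrast(a, b), -target_contrast(b, a)[names(a)])
  expect_error(target_contrast(a, c(v1 = 1, v9 = 2, v2 = 3)), "differ")
})

test_that("classifier tuning reaches perfect accuracy on separable data", {
  set.seed(11)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = 4 * y + 0.1 * stats::rnorm(n), b = stats::rnorm(n))
  for (alg in c("svm", "rf", "logreg")) {
    tc <- tune_classifier(alg, X, y, seed = 1)
    expect_equal(tc$cv_score, 1)
    expect_true(is.list(tc$params))
  }
  # the forest default cell (200 trees, depth 10) is on the grid and
  # wins ties
  tc_rf <- tune_classifier("rf", X, y, seed = 1)
  expect_equal(tc_rf$params$num_trees, 200)
  expect_equal(tc_rf$params$max_depth, 10)
  # determinism
  tc2 <- tune_classifier("svm", X, y, seed = 1)
  expect_identical(tune_classifier("svm", X, y, seed = 1), tc2)
})
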