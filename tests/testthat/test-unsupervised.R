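test_that("PCA of two perfectly correlated variables concentrates variance", {
  set.seed(1)
  x <- as.vector(scale(stats::rnorm(200)))
  Z <- cbind(a = x, b = x)
  m <- pca_project(Z)
  expect_equal(m$eigenvalues[1], 2, tolerance = 1e-6)
  expect_true(length(m$eigenvalues) == 1 || m$eigenvalues[2] < 1e-10)
  expect_equal(sum(m$explained_fraction), 1)
})

test_that("independent columns give unit eigenvalues and sign-fixed output", {
  set.seed(2)
  Z <- scale(matrix(stats::rnorm(10000 * 6), 10000, 6))
  colnames(Z) <- paste0("v", 1:6)
  m <- pca_project(Z)
  expect_true(all(abs(m$eigenvalues - 1) < 0.1))
  # sign convention: the largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(m$loadings)))
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  # deterministic: identical input, identical projection
  m2 <- pca_project(Z)
  expect_identical(m$scores, m2$scores)
})

test_that("Kaiser-Guttman retention counts eigenvalues above 1", {
  fake <- list(eigenvalues = c(3.2, 1.01, 0.99, 0.5))
  expect_equal(retain_components(fake), 2L)
  expect_warning(n <- retain_components(list(eigenvalues = c(0.9, 0.8))),
                 "retaining the largest")
  expect_equal(n, 1L)
  # synthetic two-factor data
  set.seed(3)
  f <- matrix(stats::rnorm(400 * 2), 400, 2)
  load <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 1))
  Z <- scale(f %*% t(load) + 0.4 * matrix(stats::rnorm(400 * 6), 400, 6))
  colnames(Z) <- paste0("v", 1:6)
  expect_equal(pca_project(Z)$n_retained, 2L)
})

test_that("variance-weighted importance ranks a planted signal variable first", {
  set.seed(4)
  n <- 300
  g <- rep(0:1, each = n / 2)
  Z <- cbind(signal = g * 3 + stats::rnorm(n),
             matrix(stats::rnorm(n * 5), n, 5))
  colnames(Z)[2:6] <- paste0("noise", 1:5)
  Z <- scale(Z)
  m <- pca_project(Z)
  imp <- pca_variable_importance(Z, m)
  expect_equal(names(which.max(imp)), "signal")
  expect_true(all(imp >= 0))
  expect_error(pca_variable_importance(Z, m, n_retained = 100), "exceeds")
  # full-space variant is legal
  imp_full <- pca_variable_importance(Z, m, n_retained = ncol(m$scores))
  expect_length(imp_full, ncol(Z))
})

test_that("exchangeable variables receive equal importances on average", {
  # the within-component z-transform spreads near-equal associations in
  # any single draw, so symmetry shows in the Monte-Carlo expectation
  imps <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 300
    common <- stats::rnorm(n)
    Z <- scale(vapply(1:4, function(i) common + stats::rnorm(n),
                      numeric(n)))
    colnames(Z) <- paste0("v", 1:4)
    m <- pca_project(Z)
    pca_variable_importance(Z, m)
  }, numeric(4))
  means <- rowMeans(imps)
  expect_lt(diff(range(means)) / mean(means), 0.25)
})

test_that("k-means recovers well-separated blobs and is deterministic", {
  blobs <- make_blobs(n_per = 40, separation = 10, seed = 6)
  sol <- kmeans_cluster(blobs$x, 2, seed = 1)
  expect_equal(adjusted_rand_index(sol$labels, blobs$labels), 1)
  expect_true(all(sol$labels %in% 0:1))
  expect_gt(sol$mean_silhouette, 0.8)
  expect_equal(sol$mean_silhouette, mean(sol$silhouettes))
  sol2 <- kmeans_cluster(blobs$x, 2, seed = 1)
  expect_identical(sol$labels, sol2$labels)
  # boundary legality: k = n - 1 on distinct points
  set.seed(7)
  pts <- matrix(stats::rnorm(12), 6, 2)
  sol3 <- kmeans_cluster(pts, 5, seed = 2)
  expect_length(sol3$silhouettes, 6)
  expect_error(kmeans_cluster(pts, 6, seed = 1), "smaller")
  expect_error(kmeans_cluster(pts, 1, seed = 1), "at least 2")
})

test_that("silhouette-based k selection finds planted blob counts", {
  b2 <- make_blobs(n_per = 40, separation = 8, seed = 8, k = 2)
  expect_equal(select_k_by_silhouette(b2$x, seed = 1)$best_k, 2L)
  # four blobs spread in 2D so they are genuinely distinct
  set.seed(10)
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), 4, 2, byrow = TRUE)
  x4 <- do.call(rbind, lapply(1:4, function(i)
    matrix(stats::rnorm(30 * 2), 30, 2) + centers[rep(i, 30), ]))
  expect_equal(select_k_by_silhouette(x4, seed = 1)$best_k, 4L)
  # pure noise at battery-like dimensionality: low silhouette flags
  # absent structure
  set.seed(11)
  noise <- matrix(stats::rnorm(150 * 15), 150, 15)
  ks <- select_k_by_silhouette(noise, seed = 1)
  expect_true(ks$no_structure)
  expect_lt(max(ks$mean_silhouettes), 0.1)
})

test_that("adjusted Rand index matches its definition and the brute-force oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(5, 5, 9, 9)), 1)
  set.seed(12)
  a <- sample(0:3, 1000, replace = TRUE)
  b <- sample(0:3, 1000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
  # pair-counting oracle on every small instance
  for (i in 1:100) {
    n <- sample(4:8, 1)
    la <- sample(0:2, n, replace = TRUE)
    lb <- sample(0:2, n, replace = TRUE)
    expect_equal(adjusted_rand_index(la, lb), brute_force_ari(la, lb),
                 tolerance = 1e-12)
  }
  # independent cross-check against an established implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    for (i in 1:20) {
      la <- sample(0:4, 60, replace = TRUE)
      lb <- sample(0:4, 60, replace = TRUE)
      expect_equal(adjusted_rand_index(la, lb),
                   mclust::adjustedRandIndex(la, lb), tolerance = 1e-12)
    }
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("bootstrap stability is high for separated blobs, low for noise", {
  blobs <- make_blobs(n_per = 40, separation = 10, seed = 13)
  sol <- kmeans_cluster(blobs$x, 2, seed = 1)
  st <- bootstrap_stability(blobs$x, sol$labels, n_runs = 20, seed = 1)
  expect_gt(st$mean_ari, 0.95)
  expect_equal(st$n_runs, 20)
  expect_length(st$ari_per_run, 20)
  set.seed(14)
  noise <- matrix(stats::rnorm(120 * 15), 120, 15)
  nsol <- kmeans_cluster(noise, 2, seed = 1)
  stn <- bootstrap_stability(noise, nsol$labels, n_runs = 20, seed = 1)
  expect_lt(stn$mean_ari, 0.3)
})

test_that("clusterer comparison favors k-means on spherical blobs", {
  blobs <- make_blobs(n_per = 40, separation = 10, seed = 15)
  cmp <- compare_clusterers(blobs$x, 2, seed = 1)
  expect_setequal(cmp$method, c("kmeans", "ward", "pam"))
  km <- cmp$mean_silhouette[cmp$method == "kmeans"]
  expect_true(all(km >= cmp$mean_silhouette - 1e-9))
  cmp2 <- compare_clusterers(blobs$x, 2, seed = 1)
  expect_identical(cmp, cmp2)
  # degenerate but legal: k = 2 on 3 points
  cmp3 <- compare_clusterers(matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE),
                             2, seed = 1)
  expect_equal(nrow(cmp3), 3)
})
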