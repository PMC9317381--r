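#' Principal components projection of standardized olfaction data
#'
#' Eigen-decomposition of the sample covariance of the z-standardized
#' variables (equivalently their correlation structure). Component signs
#' are fixed so that each component's largest-magnitude loading is
#' positive, making the output deterministic. Eigenvalues numerically at
#' zero are truncated.
#'
#' @param z_mat complete numeric matrix of z-standardized variables
#'   (subjects x variables).
#' @return object of class `pca_model`: `loadings` (variables x
#'   components), `eigenvalues`, `explained_fraction`, `scores`
#'   (subjects x components), `n_retained` (Kaiser-Guttman count).
#' @export
pca_project <- function(z_mat) {
  z_mat <- as.matrix(z_mat)
  if (any(!is.finite(z_mat))) stop("non-finite entries in input")
  pc <- stats::prcomp(z_mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  model <- structure(
    list(loadings = load, eigenvalues = ev,
         explained_fraction = ev / sum(ev), scores = scores),
    class = "pca_model")
  model$n_retained <- retain_components(model)
  model
}

#' Kaiser-Guttman component retention
#'
#' Number of eigenvalues strictly greater than 1. If none exceeds 1 the
#' largest component is retained with a warning so downstream stages
#' always have at least one dimension.
#'
#' @param model a [pca_project()] result.
#' @return integer count of retained components.
#' @export
retain_components <- function(model) {
  n <- sum(model$eigenvalues > 1)
  if (n == 0) {
    warning("no eigenvalue exceeds 1; retaining the largest component")
    n <- 1L
  }
  as.integer(n)
}

#' Variance-weighted PCA variable importance
#'
#' For each variable and component, the dot product of the z-scored
#' variable with the component's score vector is computed; the resulting
#' variables x components association matrix is z-transformed within each
#' component (column-wise, preserving cross-variable comparability) and
#' each column is weighted by that component's explained-variance
#' fraction. A variable's importance is the absolute row sum over the
#' retained components (the signed version is attached as an attribute,
#' since row sums can be negative while downstream ABC categorization
#' requires positive data).
#'
#' @param z_mat the standardized matrix the model was fitted on.
#' @param model a [pca_model].
#' @param n_retained number of leading components to sum over; defaults
#'   to the model's Kaiser-Guttman count. Use `ncol(model$scores)` for
#'   the full-space variant.
#' @return named nonnegative numeric vector with attribute `"signed"`.
#' @export
pca_variable_importance <- function(z_mat, model,
                                    n_retained = model$n_retained) {
  if (n_retained > ncol(model$scores))
    stop("n_retained exceeds the number of available components")
  D <- crossprod(as.matrix(z_mat), model$scores)  # variables x components
  D <- scale(D)  # z-transform within component
  D <- sweep(D, 2, model$explained_fraction, `*`)
  signed <- rowSums(D[, seq_len(n_retained), drop = FALSE])
  imp <- abs(signed)
  attr(imp, "signed") <- signed
  imp
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  min_d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    idx <- if (all(min_d2 == 0)) sample.int(n, 1)
    else sample.int(n, 1, prob = min_d2)
    centers[j + 1, ] <- x[idx, ]
    d2 <- rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2)
    min_d2 <- pmin(min_d2, d2)
  }
  centers
}

#' K-means clustering with silhouette diagnostics
#'
#' Lloyd's algorithm with k-means++ initialization, 25 restarts (best
#' within-cluster sum of squares kept), Euclidean distance, and
#' per-subject silhouette widths. Labels are reported 0-based (clusters
#' `0..k-1`) to match the phenotype-cluster naming convention.
#'
#' @param scores numeric matrix (e.g. retained PC scores).
#' @param k number of clusters, `2 <= k < n`.
#' @param seed integer seed; identical seeds give identical labels.
#' @param nstart restarts (default 25).
#' @return object of class `cluster_solution`: `k`, `labels` (0-based),
#'   `centers`, `silhouettes`, `mean_silhouette`, `tot_withinss`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1L, nstart = 25) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 2) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of subjects")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- NULL
    for (try in 1:10) {
      init <- kmeanspp_init(scores, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(scores, centers = init,
                                       iter.max = 300,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce a valid solution")
  sil <- cluster::silhouette(best$cluster, stats::dist(scores))
  silw <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, n)
  structure(list(k = as.integer(k), labels = best$cluster - 1L,
                 centers = best$centers, silhouettes = silw,
                 mean_silhouette = mean(silw),
                 tot_withinss = best$tot.withinss),
            class = "cluster_solution")
}

#' Select the number of clusters by mean silhouette width
#'
#' Fits k-means for every k in `k_range` and returns the k maximizing the
#' mean silhouette width (ties broken toward the smaller k). When even
#' the best mean silhouette falls below `min_silhouette` the result is
#' flagged as showing no reliable cluster structure.
#'
#' @param scores numeric matrix of projected data.
#' @param k_range candidate cluster counts (default 2:5).
#' @param seed integer seed.
#' @param min_silhouette "no structure" flag threshold (default 0.1).
#' @return list with `best_k`, `solutions` (one [kmeans_cluster()] result
#'   per k), `mean_silhouettes`, and logical `no_structure`.
#' @export
select_k_by_silhouette <- function(scores, k_range = 2:5, seed = 1L,
                                   min_silhouette = 0.1) {
  if (nrow(as.matrix(scores)) <= max(k_range))
    stop("not enough subjects for the requested k range")
  solutions <- lapply(seq_along(k_range), function(i)
    kmeans_cluster(scores, k_range[i], seed = seed + i))
  ms <- vapply(solutions, `[[`, numeric(1), "mean_silhouette")
  best <- which.max(ms)  # which.max takes the first maximum: smaller k
  list(best_k = as.integer(k_range[best]), solutions = solutions,
       mean_silhouettes = stats::setNames(ms, paste0("k", k_range)),
       no_structure = ms[best] < min_silhouette)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model, computed from
#' the contingency table: 1 for identical partitions (up to label names),
#' about 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return numeric value, at most 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Bootstrap stability of a clustering solution
#'
#' Draws `n_runs` bootstrap resamples of the subjects, re-clusters each
#' at the reference k, and records (a) the mean silhouette width of the
#' resample's solution and (b) the adjusted Rand index between the
#' resample labels and the reference labels, evaluated on the unique
#' resampled subjects. A degenerate resample that collapses to a single
#' effective cluster scores ARI 0 for that run.
#'
#' @param scores numeric matrix the reference solution was fitted on.
#' @param reference_labels labels of the reference solution.
#' @param n_runs bootstrap runs (default 20).
#' @param seed integer seed.
#' @return object of class `stability_report`: per-run silhouettes and
#'   ARIs plus their means.
#' @export
bootstrap_stability <- function(scores, reference_labels, n_runs = 20,
                                seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- length(unique(reference_labels))
  sil <- ari <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    idx <- sample.int(n, n, replace = TRUE)
    sol <- kmeans_cluster(scores[idx, , drop = FALSE], k, seed = seed + r)
    sil[r] <- sol$mean_silhouette
    u <- !duplicated(idx)
    run_lab <- sol$labels[u]
    ref_lab <- reference_labels[idx[u]]
    ari[r] <- if (length(unique(run_lab)) < 2 || length(unique(ref_lab)) < 2) 0
    else adjusted_rand_index(run_lab, ref_lab)
  }
  structure(list(n_runs = n_runs, silhouette_per_run = sil,
                 ari_per_run = ari, mean_silhouette = mean(sil),
                 mean_ari = mean(ari)),
            class = "stability_report")
}

#' Compare clustering methods by mean silhouette width
#'
#' Fits k-means, Ward agglomerative clustering and partitioning around
#' medoids at the same k and reports the same Euclidean mean silhouette
#' width for each, for an apples-to-apples comparison.
#'
#' @param scores numeric matrix.
#' @param k number of clusters.
#' @param seed integer seed (used by k-means only; the other two are
#'   deterministic).
#' @return data.frame with columns `method` and `mean_silhouette`.
#' @export
compare_clusterers <- function(scores, k, seed = 1L) {
  scores <- as.matrix(scores)
  d <- stats::dist(scores)
  msil <- function(lab) {
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }
  km <- kmeans_cluster(scores, k, seed = seed)
  ward <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
  pam <- cluster::pam(d, k = k, cluster.only = TRUE)
  data.frame(
    method = c("kmeans", "ward", "pam"),
    mean_silhouette = c(km$mean_silhouette, msil(ward), msil(pam)))
}
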