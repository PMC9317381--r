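#' Repeated stratified cross-validation scheme
#'
#' @param n_splits folds per repeat (default 5).
#' @param n_repeats repeats (default 20); total runs =
#'   `n_splits * n_repeats` (100 by default).
#' @param seed integer seed.
#' @return object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_splits = 5, n_repeats = 20, seed = 1L) {
  structure(list(n_splits = n_splits, n_repeats = n_repeats,
                 seed = as.integer(seed),
                 n_runs = n_splits * n_repeats),
            class = "cv_scheme")
}

# list of train-index vectors, one per run
scheme_runs <- function(y, scheme) {
  runs <- list()
  for (rep in seq_len(scheme$n_repeats)) {
    folds <- stratified_folds(y, scheme$n_splits,
                              seed = scheme$seed + 7919L * rep)
    for (f in seq_len(scheme$n_splits))
      runs[[length(runs) + 1]] <- list(train = which(folds != f),
                                       test = which(folds == f))
  }
  runs
}

#' Stratified holdout split
#'
#' Puts aside a fixed fraction of each group as a validation sample that
#' must not be touched during tuning and feature selection.
#'
#' @param labels group membership vector.
#' @param fraction validation fraction per group (default 0.2).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors `train` and `validation`.
#' @export
holdout_split <- function(labels, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  set.seed(seed)
  validation <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- round(fraction * length(idx))
    if (n_val < 1 || length(idx) - n_val < 4)
      stop("group too small to stratify at this fraction")
    validation <- c(validation, sample(idx, n_val))
  }
  validation <- sort(validation)
  list(train = setdiff(seq_along(labels), validation),
       validation = validation)
}

# one-way F statistic per column for a two-group comparison
f_statistic <- function(X, y) {
  y <- factor(y)
  n <- nrow(X)
  k <- nlevels(y)
  gm <- colMeans(X)
  ss_between <- 0
  ss_within <- 0
  for (cl in levels(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    ss_between <- ss_between + nrow(Xi) * (mi - gm)^2
    ss_within <- ss_within + colSums((Xi - matrix(mi, nrow(Xi), ncol(Xi),
                                                  byrow = TRUE))^2)
  }
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# tune SelectKBest's k once per algorithm by 5-fold CV balanced accuracy
# over k = 1..p on the training set
tune_skb_k <- function(algorithm, X, y, params, seed) {
  p <- ncol(X)
  folds <- stratified_folds(y, 5, seed)
  Fv <- f_statistic(X, y)
  ord <- order(-Fv)
  scores <- vapply(seq_len(p), function(k)
    cv_balanced_accuracy(algorithm, X[, ord[seq_len(k)], drop = FALSE],
                         y, params, folds, seed), numeric(1))
  which.max(scores)
}

# greedy sequential selection evaluated on the run's held-out fold
sfs_select <- function(algorithm, Xtr, ytr, Xte, yte, params, seed,
                       forward = TRUE, tol = 1e-4) {
  p <- ncol(Xtr)
  current <- if (forward) integer(0) else seq_len(p)
  score_set <- function(set) {
    if (length(set) == 0) return(0.5)
    model <- fit_classifier(algorithm, Xtr[, set, drop = FALSE], ytr,
                            params, seed = seed)
    balanced_accuracy(yte, predict_classifier(model, Xte[, set, drop = FALSE]))
  }
  best_score <- score_set(current)
  repeat {
    cands <- if (forward) setdiff(seq_len(p), current) else current
    if (length(cands) == 0 || (!forward && length(current) <= 1)) break
    cand_scores <- vapply(cands, function(j) {
      set <- if (forward) c(current, j) else setdiff(current, j)
      score_set(set)
    }, numeric(1))
    j <- which.max(cand_scores)
    if (cand_scores[j] > best_score + tol) {
      best_score <- cand_scores[j]
      current <- if (forward) c(current, cands[j])
      else setdiff(current, cands[j])
    } else break
  }
  sort(current)
}

#' Run one model-based feature-selection method over a CV scheme
#'
#' Applies one of the five selection schemes with one of the three
#' algorithms in every run of a repeated stratified k-fold scheme and
#' counts, per variable, how often it was selected:
#' \describe{
#'   \item{SKB}{top-k variables by one-way F statistic, with k tuned
#'     once per algorithm by cross-validated balanced accuracy over
#'     `1..p` on the full training set.}
#'   \item{SFM}{variables whose model importance exceeds the mean
#'     importance of the run's fitted model.}
#'   \item{RFE}{recursive elimination of the least important variable
#'     until half remain.}
#'   \item{SFSf / SFSb}{greedy forward (from empty) / backward (from
#'     full) sequential selection maximizing balanced accuracy on the
#'     run's held-out fold, stopping when no step improves by more than
#'     1e-4.}
#' }
#'
#' @param method `"SKB"`, `"SFM"`, `"RFE"`, `"SFSf"` or `"SFSb"`.
#' @param algorithm `"svm"`, `"rf"` or `"logreg"`.
#' @param X training feature matrix (holdout already removed).
#' @param y training labels.
#' @param params tuned hyperparameters for the algorithm
#'   (see [tune_classifier()]).
#' @param scheme a [cv_scheme()].
#' @return named integer vector of per-variable selection counts
#'   (maximum = number of runs).
#' @export
run_selection_method <- function(method, algorithm, X, y, params,
                                 scheme = cv_scheme()) {
  X <- as.matrix(X)
  y <- factor(y)
  p <- ncol(X)
  counts <- stats::setNames(integer(p), colnames(X))
  runs <- scheme_runs(y, scheme)
  skb_k <- if (method == "SKB")
    tune_skb_k(algorithm, X, y, params, scheme$seed) else NULL
  for (r in seq_along(runs)) {
    tr <- runs[[r]]$train
    te <- runs[[r]]$test
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    run_seed <- scheme$seed + 104729L * r
    sel <- switch(
      method,
      SKB = {
        Fv <- f_statistic(Xtr, ytr)
        order(-Fv)[seq_len(skb_k)]
      },
      SFM = {
        model <- fit_classifier(algorithm, Xtr, ytr, params, run_seed)
        imp <- classifier_importance(model)
        which(imp > mean(imp))
      },
      RFE = {
        remaining <- seq_len(p)
        target <- ceiling(p / 2)
        while (length(remaining) > target) {
          model <- fit_classifier(algorithm, Xtr[, remaining, drop = FALSE],
                                  ytr, params, run_seed)
          imp <- classifier_importance(model)
          remaining <- remaining[-which.min(imp)]
        }
        remaining
      },
      SFSf = sfs_select(algorithm, Xtr, ytr,
                        X[te, , drop = FALSE], y[te], params, run_seed,
                        forward = TRUE),
      SFSb = sfs_select(algorithm, Xtr, ytr,
                        X[te, , drop = FALSE], y[te], params, run_seed,
                        forward = FALSE),
      stop("unknown method: ", method))
    counts[sel] <- counts[sel] + 1L
  }
  counts
}

#' Consolidate one method's result into its ABC set A
#'
#' Applies computed ABC analysis to a method's nonnegative per-variable
#' record (selection counts for the model-based methods, absolute
#' importances or absolute effect sizes for the two univariate ones) and
#' returns the "important few".
#'
#' @param values named nonnegative vector.
#' @return character vector of set-A variable names.
#' @export
consolidate_method <- function(values) {
  if (all(values == 0)) stop("all-zero record cannot be consolidated")
  abc_set_a(values)
}

#' The 17-method feature-selection ensemble
#'
#' Runs PCA-based variable importance, Cohen's d effect sizes, and five
#' model-based selection schemes (SKB, SFM, RFE, forward and backward
#' SFS) with each of three algorithms (linear max-margin classifier,
#' random forest, penalized logistic regression) over a repeated
#' stratified cross-validation scheme; consolidates each method's record
#' into its ABC set A; and forms the final reduced feature set as the
#' ABC set A of the per-variable sum of A-memberships (range 0..17).
#' The PCA method sees only the olfaction variables, so age, sex and BMI
#' are structural zeros in its row.
#'
#' @param X training feature matrix (z-scored olfaction variables plus
#'   covariates; holdout removed), with column names.
#' @param y training cluster (or diagnosis) labels.
#' @param olfaction character vector of the columns that are olfaction
#'   variables (the PCA method's domain).
#' @param tuned named list of tuned hyperparameters per algorithm, as
#'   returned by [tune_classifier()]; tuned on demand when omitted.
#' @param scheme a [cv_scheme()].
#' @param seed integer seed for on-demand tuning.
#' @return object of class `selection_matrix`: `methods`, `counts`
#'   (17 x p, `NA` for the two non-counting methods), `a_membership`
#'   (17 x p logical), `sum_score`, `final_set`.
#' @export
feature_selection_ensemble <- function(X, y, olfaction = colnames(X),
                                       tuned = NULL,
                                       scheme = cv_scheme(), seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  p <- ncol(X)
  vars <- colnames(X)
  algorithms <- c(svm = "svm", rf = "rf", logreg = "logreg")
  if (is.null(tuned))
    tuned <- lapply(algorithms, function(a)
      tune_classifier(a, X, y, seed = seed)$params)

  methods <- c("PCA", "CohensD",
               as.vector(outer(c("SKB", "SFM", "RFE", "SFSf", "SFSb"),
                               c("SVM", "RF", "LogReg"), paste, sep = "_")))
  counts <- matrix(NA_real_, length(methods), p,
                   dimnames = list(methods, vars))
  a_mem <- matrix(FALSE, length(methods), p,
                  dimnames = list(methods, vars))

  # (i) PCA variable importance, olfaction columns only
  Zo <- X[, olfaction, drop = FALSE]
  model <- pca_project(Zo)
  imp <- pca_variable_importance(Zo, model)
  a_mem["PCA", consolidate_method(imp)] <- TRUE

  # (ii) absolute Cohen's d per variable
  groups <- levels(y)
  dvec <- vapply(vars, function(v)
    abs(cohens_d(X[y == groups[1], v], X[y == groups[2], v])), numeric(1))
  a_mem["CohensD", consolidate_method(dvec)] <- TRUE

  # (iii)-(vi) the 15 model-based method x algorithm combinations
  alg_label <- c(svm = "SVM", rf = "RF", logreg = "LogReg")
  for (alg in algorithms) {
    for (m in c("SKB", "SFM", "RFE", "SFSf", "SFSb")) {
      row <- paste(m, alg_label[[alg]], sep = "_")
      cnt <- run_selection_method(m, alg, X, y, tuned[[alg]], scheme)
      counts[row, ] <- cnt
      if (any(cnt > 0))
        a_mem[row, consolidate_method(cnt)] <- TRUE
    }
  }

  sum_score <- colSums(a_mem)
  structure(list(methods = methods, counts = counts, a_membership = a_mem,
                 sum_score = sum_score,
                 final_set = abc_set_a(sum_score),
                 scheme = scheme, tuned = tuned),
            class = "selection_matrix")
}

#' @export
print.selection_matrix <- function(x, ...) {
  cat(sprintf("selection_matrix: %d methods x %d variables\n",
              length(x$methods), length(x$sum_score)))
  cat("final reduced set:", paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}

#' Consolidate a selection matrix into the final reduced set
#'
#' Row sums of the per-method ABC set-A memberships give each variable a
#' sum score between 0 and 17; computed ABC analysis of the sum scores
#' yields the final reduced feature set.
#'
#' @param matrix a `selection_matrix` from [feature_selection_ensemble()].
#' @return list with `sum_score` and `final_set`.
#' @export
ensemble_consolidate <- function(matrix) {
  stopifnot(inherits(matrix, "selection_matrix"))
  if (nrow(matrix$a_membership) != length(matrix$methods))
    stop("selection matrix is missing method rows")
  sum_score <- colSums(matrix$a_membership)
  list(sum_score = sum_score, final_set = abc_set_a(sum_score))
}

#' Contrast of selection sum scores between two targets
#'
#' Difference of the per-variable ensemble sum scores obtained for two
#' different targets (e.g. detected clusters versus clinical diagnosis):
#' positive values mark variables selected more often for the first
#' target.
#'
#' @param sums_cluster,sums_diagnosis named sum-score vectors over the
#'   same variables.
#' @return named numeric vector of differences.
#' @export
target_contrast <- function(sums_cluster, sums_diagnosis) {
  if (!identical(sort(names(sums_cluster)), sort(names(sums_diagnosis))))
    stop("variable sets differ between the two ensembles")
  sums_cluster - sums_diagnosis[names(sums_cluster)]
}
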