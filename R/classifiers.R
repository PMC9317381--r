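# Unified interface over the three classification algorithms used by the
# feature-selection ensemble and the holdout validation: a linear
# max-margin classifier (libsvm via e1071), random forests (ranger), and
# penalized logistic regression (glmnet). All fits are deterministic
# given the seed and run single-threaded.

fit_classifier <- function(algorithm, X, y, params, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2 || min(table(y)) < 1)
    return(structure(list(constant = names(which.max(table(y))),
                          levels = levels(y)),
                     class = "olf_constant"))
  if (algorithm == "svm") {
    set.seed(seed)
    fit <- e1071::svm(X, y, kernel = "linear", cost = params$cost,
                      scale = FALSE)
    structure(list(fit = fit, levels = levels(y)), class = "olf_svm")
  } else if (algorithm == "rf") {
    fit <- ranger::ranger(
      x = as.data.frame(X), y = y,
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      importance = "impurity", seed = seed, num.threads = 1)
    structure(list(fit = fit, levels = levels(y)), class = "olf_rf")
  } else if (algorithm == "logreg") {
    if (ncol(X) >= 2) {
      fit <- glmnet::glmnet(X, y, family = "binomial",
                            alpha = params$alpha, lambda = params$lambda)
      structure(list(fit = fit, levels = levels(y), penalized = TRUE),
                class = "olf_logreg")
    } else {
      # glmnet needs >= 2 predictors; a single-variable model is fitted
      # unpenalized
      df <- data.frame(y = y, X)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      structure(list(fit = fit, levels = levels(y), penalized = FALSE,
                     vars = colnames(X)),
                class = "olf_logreg")
    }
  } else stop("unknown algorithm: ", algorithm)
}

predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  if (inherits(model, "olf_constant"))
    return(factor(rep(model$constant, nrow(X)), levels = model$levels))
  if (inherits(model, "olf_svm"))
    return(stats::predict(model$fit, X))
  if (inherits(model, "olf_rf"))
    return(stats::predict(model$fit, data = as.data.frame(X))$predictions)
  if (inherits(model, "olf_logreg")) {
    if (isTRUE(model$penalized)) {
      cls <- stats::predict(model$fit, X, type = "class")
      return(factor(as.vector(cls), levels = model$levels))
    }
    pr <- stats::predict(model$fit,
                         newdata = as.data.frame(X), type = "response")
    return(factor(model$levels[1 + (pr > 0.5)], levels = model$levels))
  }
  stop("unknown model class")
}

# per-variable importance of a fitted model: |hyperplane weight| for the
# margin classifier, impurity decrease for forests, |coefficient| for
# logistic regression
classifier_importance <- function(model) {
  if (inherits(model, "olf_constant"))
    stop("constant model has no usable importances")
  if (inherits(model, "olf_svm")) {
    w <- crossprod(model$fit$SV, model$fit$coefs)
    return(abs(drop(w)))
  }
  if (inherits(model, "olf_rf"))
    return(model$fit$variable.importance)
  if (inherits(model, "olf_logreg")) {
    if (isTRUE(model$penalized))
      return(abs(as.vector(stats::coef(model$fit))[-1]))
    return(abs(stats::coef(model$fit)[-1]))
  }
  stop("unknown model class")
}

# stratified fold assignment: within each class, subjects are shuffled
# and dealt round-robin into k folds
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

cv_balanced_accuracy <- function(algorithm, X, y, params, folds, seed) {
  k <- max(folds)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) { acc[f] <- NA; next }
    model <- fit_classifier(algorithm, X[tr, , drop = FALSE], y[tr],
                            params, seed = seed + f)
    pred <- predict_classifier(model, X[!tr, , drop = FALSE])
    acc[f] <- balanced_accuracy(y[!tr], pred)
  }
  mean(acc, na.rm = TRUE)
}

tuning_grid <- function(algorithm) {
  if (algorithm == "svm") {
    # L2-regularized hinge loss; the grid walks the penalty strength
    data.frame(cost = c(1, 10^c(-3:-1, 1:3)))
  } else if (algorithm == "rf") {
    # preferred cell (200 trees, depth 10) first so ties resolve to it
    g <- expand.grid(num_trees = c(200, 100), max_depth = c(10, 5, 0))
    g[order(g$num_trees != 200 | g$max_depth != 10), ]
  } else if (algorithm == "logreg") {
    # ridge (alpha 0) cells precede LASSO so ties resolve to ridge
    expand.grid(lambda = 10^(-3:3), alpha = c(0, 1))
  } else stop("unknown algorithm: ", algorithm)
}

#' Tune a classifier by cross-validated grid search
#'
#' 5-fold stratified cross-validated grid search selecting by mean
#' balanced accuracy. Grids: penalty strength `10^-3..10^3` for the
#' linear models, with the logistic model additionally choosing between
#' ridge (L2) and LASSO (L1) penalties; forest size \{100, 200\} times
#' maximum depth \{5, 10, unlimited\} for random forests. Ties resolve
#' to ridge for the logistic model and to 200 trees of depth 10 for the
#' forest.
#'
#' @param algorithm `"svm"` (linear max-margin), `"rf"` (random forest)
#'   or `"logreg"` (penalized logistic regression).
#' @param X numeric feature matrix (training data only).
#' @param y two-class label vector.
#' @param seed integer seed (fold assignment and fits).
#' @param n_folds grid-search folds (default 5).
#' @return list with `algorithm`, `params` (chosen grid row as a list)
#'   and `cv_score`.
#' @export
tune_classifier <- function(algorithm, X, y, seed = 1L, n_folds = 5) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("both classes required for tuning")
  grid <- tuning_grid(algorithm)
  folds <- stratified_folds(y, n_folds, seed)
  scores <- vapply(seq_len(nrow(grid)), function(i)
    cv_balanced_accuracy(algorithm, X, y, as.list(grid[i, , drop = FALSE]),
                         folds, seed), numeric(1))
  best <- which.max(scores)  # first maximum: the preferred cell wins ties
  list(algorithm = algorithm, params = as.list(grid[best, , drop = FALSE]),
       cv_score = scores[best])
}
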