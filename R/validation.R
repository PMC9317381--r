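#' Balanced accuracy
#'
#' Mean of the per-class recalls; 0.5 is chance level for two classes
#' regardless of class imbalance.
#'
#' @param y_true true labels (every class present at least once).
#' @param y_pred predicted labels of the same length.
#' @return numeric in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  classes <- unique(y_true)
  if (length(classes) < 1) stop("no true classes")
  recalls <- vapply(classes, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1))
  if (anyNA(recalls)) stop("a true class is absent")
  mean(recalls)
}

stratified_subsample <- function(y, fraction) {
  idx <- integer(0)
  for (cl in unique(y)) {
    cl_idx <- which(y == cl)
    n_take <- max(1, round(fraction * length(cl_idx)))
    idx <- c(idx, sample(cl_idx, n_take))
  }
  sort(idx)
}

#' Validate feature sets on held-out data by balanced accuracy
#'
#' For each run, a stratified random 80% of the training subjects is
#' used to fit every classifier on every feature set, and the fits are
#' scored on a stratified random 80% of the untouched validation
#' subjects. Reported per cell are the median balanced accuracy and its
#' nonparametric 95% confidence interval (2.5th to 97.5th percentiles)
#' over the runs. A cell is flagged unstable when more than half of its
#' runs lacked a class in the validation subsample.
#'
#' @param X_train,y_train training features and labels.
#' @param X_val,y_val validation features and labels (disjoint subjects).
#' @param feature_sets named list of character vectors of column names,
#'   e.g. `list(full = ..., reduced = ..., sparse = ...)`.
#' @param tuned named list of tuned hyperparameters per algorithm
#'   (see [tune_classifier()]).
#' @param algorithms algorithms to evaluate (default all three).
#' @param n_runs evaluation runs (default 100).
#' @param fraction subsample fraction per run (default 0.8).
#' @param seed integer seed.
#' @return object of class `validation_report`: data.frame `cells` with
#'   columns classifier, feature_set, median, ci_lo, ci_hi, unstable;
#'   plus the raw run-level accuracies in `runs`.
#' @export
validate_feature_sets <- function(X_train, y_train, X_val, y_val,
                                  feature_sets, tuned,
                                  algorithms = c("svm", "rf", "logreg"),
                                  n_runs = 100, fraction = 0.8, seed = 1L) {
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val)
  y_train <- factor(y_train)
  y_val <- factor(y_val, levels = levels(y_train))
  acc <- array(NA_real_,
               dim = c(length(algorithms), length(feature_sets), n_runs),
               dimnames = list(algorithms, names(feature_sets), NULL))
  degenerate <- matrix(0L, length(algorithms), length(feature_sets),
                       dimnames = list(algorithms, names(feature_sets)))
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    tr_idx <- stratified_subsample(y_train, fraction)
    val_idx <- stratified_subsample(y_val, fraction)
    yt <- y_train[tr_idx]
    yv <- y_val[val_idx]
    for (alg in algorithms) {
      for (fs in names(feature_sets)) {
        vars <- feature_sets[[fs]]
        if (length(unique(yv)) < 2) {
          degenerate[alg, fs] <- degenerate[alg, fs] + 1L
          next
        }
        model <- fit_classifier(alg, X_train[tr_idx, vars, drop = FALSE],
                                yt, tuned[[alg]], seed = seed + r)
        pred <- predict_classifier(model, X_val[val_idx, vars, drop = FALSE])
        acc[alg, fs, r] <- balanced_accuracy(as.character(yv),
                                             as.character(pred))
      }
    }
  }
  cells <- expand.grid(classifier = algorithms,
                       feature_set = names(feature_sets),
                       stringsAsFactors = FALSE)
  stats_df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    a <- acc[cells$classifier[i], cells$feature_set[i], ]
    q <- stats::quantile(a, c(0.5, 0.025, 0.975), na.rm = TRUE)
    data.frame(classifier = cells$classifier[i],
               feature_set = cells$feature_set[i],
               median = unname(q[1]), ci_lo = unname(q[2]),
               ci_hi = unname(q[3]),
               unstable = degenerate[cells$classifier[i],
                                     cells$feature_set[i]] > n_runs / 2)
  }))
  structure(list(cells = stats_df, runs = acc, n_runs = n_runs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  df <- x$cells
  df$summary <- sprintf("%.2f (%.2f-%.2f)", df$median, df$ci_lo, df$ci_hi)
  print(df[, c("classifier", "feature_set", "summary")], row.names = FALSE)
  invisible(x)
}
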