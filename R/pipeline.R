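#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end analysis: input (a cohort CSV
#' plus sidecar, or a synthetic-cohort configuration), the master seed,
#' contingency-test correction, the cluster-number search range, the
#' cross-validation scheme, and run sizes for the stability and
#' validation stages. The stages form a fixed DAG:
#' preprocess -> structure -> stats -> selection -> validation.
#'
#' @param input path to a cohort CSV (with YAML sidecar) or `NULL` to
#'   generate a synthetic cohort.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param seed master seed; every random draw in the run derives from it.
#' @param k_range candidate cluster numbers (default 2:5).
#' @param yates Yates correction for observed contingency tables
#'   (default `TRUE`).
#' @param scheme a [cv_scheme()] for the feature-selection ensemble.
#' @param stability_runs bootstrap runs for cluster stability
#'   (default 20).
#' @param validation_runs evaluation runs for the holdout validation
#'   (default 100).
#' @param run_selection,run_validation stage toggles; the later stages
#'   of the DAG can be switched off for quick structural runs.
#' @param output_dir directory for per-stage artifacts, or `NULL` to
#'   skip writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_config(),
                       seed = 1L, k_range = 2:5, yates = TRUE,
                       scheme = NULL, stability_runs = 20,
                       validation_runs = 100, run_selection = TRUE,
                       run_validation = TRUE, output_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(scheme)) scheme <- cv_scheme(seed = seed + 400L)
  structure(list(input = input, synthetic = synthetic, seed = seed,
                 k_range = k_range, yates = yates, scheme = scheme,
                 stability_runs = stability_runs,
                 validation_runs = validation_runs,
                 run_selection = run_selection,
                 run_validation = run_validation,
                 output_dir = output_dir),
            class = "run_config")
}

# classifier feature matrix: z-scored olfaction block plus z-scored age
# and BMI and the raw 0/1 sex indicator
feature_matrix <- function(ztab) {
  X <- olfaction_matrix(ztab)
  cov <- intersect(c("age", "sex", "bmi"), covariate_vars(ztab))
  for (v in cov) {
    col <- ztab$values[, v]
    if (v != "sex") col <- as.vector(scale(col))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }
  X
}

#' Run the full phenotype-structure-discovery pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation or CSV
#' input), distribution-aware preprocessing (Tukey ladder transforms,
#' 20% missingness rule, chained random-forest imputation,
#' z-standardization), unsupervised structure detection (PCA with
#' Kaiser-Guttman retention, variance-weighted variable importance with
#' ABC categorization, silhouette-selected k-means, bootstrap stability,
#' alternative-clusterer comparison), nonparametric group statistics
#' with Bonferroni correction, the 17-method feature-selection ensemble
#' with ABC consolidation, and holdout validation of the full/reduced/
#' sparse feature sets by balanced accuracy. Re-running with the same
#' configuration reproduces the report exactly.
#'
#' @param config a [run_config()].
#' @return a list report with one element per stage.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  # --- acquire -------------------------------------------------------
  truth <- NULL
  if (is.null(config$input)) {
    syn <- config$synthetic
    syn$seed <- seed
    gen <- generate_cohort(syn)
    table <- gen$table
    truth <- gen$labels
  } else {
    table <- read_cohort_csv(config$input)
  }
  n_missing <- sum(is.na(table$values))

  # --- preprocess ----------------------------------------------------
  pre <- preprocess_cohort(table, seed = seed + 100L)
  ztab <- z_standardize(pre)
  Z <- olfaction_matrix(ztab)

  # --- unsupervised structure ---------------------------------------
  model <- pca_project(Z)
  importance <- pca_variable_importance(Z, model)
  importance_abc <- abc_analysis(importance)
  ksel <- select_k_by_silhouette(model$scores[, seq_len(model$n_retained),
                                              drop = FALSE],
                                 k_range = config$k_range,
                                 seed = seed + 200L)
  solution <- ksel$solutions[[match(ksel$best_k, config$k_range)]]
  proj <- model$scores[, seq_len(model$n_retained), drop = FALSE]
  stability <- bootstrap_stability(proj, solution$labels,
                                   n_runs = config$stability_runs,
                                   seed = seed + 300L)
  clusterers <- compare_clusterers(proj, ksel$best_k, seed = seed + 250L)

  # --- group statistics ---------------------------------------------
  comparison <- compare_groups(pre, solution$labels, yates = config$yates)

  report <- list(
    seed = seed,
    n_subjects = nrow(table$values),
    n_missing_cells = n_missing,
    transforms = pre$transforms,
    pca = list(eigenvalues = model$eigenvalues,
               explained_fraction = model$explained_fraction,
               n_retained = model$n_retained,
               explained_by_retained =
                 sum(model$explained_fraction[seq_len(model$n_retained)]),
               importance = importance,
               importance_set_a = names(importance)[importance_abc$sets == "A"]),
    clustering = list(best_k = ksel$best_k,
                      mean_silhouettes = ksel$mean_silhouettes,
                      no_structure = ksel$no_structure,
                      labels = solution$labels,
                      mean_silhouette = solution$mean_silhouette,
                      cluster_sizes = as.vector(table(solution$labels)),
                      stability = stability,
                      clusterer_comparison = clusterers),
    comparison = comparison)
  if (!is.null(truth))
    report$clustering$ari_vs_truth <-
      adjusted_rand_index(solution$labels, truth[pre$subject_ids])

  # --- feature selection ensemble -----------------------------------
  if (config$run_selection) {
    X <- feature_matrix(ztab)
    y <- factor(solution$labels)
    split <- holdout_split(solution$labels, fraction = 0.2,
                           seed = seed + 500L)
    tuned <- lapply(c(svm = "svm", rf = "rf", logreg = "logreg"),
                    function(a) tune_classifier(
                      a, X[split$train, , drop = FALSE], y[split$train],
                      seed = seed + 600L)$params)
    scheme <- config$scheme
    selmat <- feature_selection_ensemble(
      X[split$train, , drop = FALSE], y[split$train],
      olfaction = olfaction_vars(ztab), tuned = tuned, scheme = scheme)
    report$selection <- list(matrix = selmat,
                             sum_score = selmat$sum_score,
                             final_set = selmat$final_set,
                             holdout = split, tuned = tuned)

    # --- holdout validation -----------------------------------------
    if (config$run_validation) {
      sparse <- intersect(c("score_pea", "score_eug"), colnames(X))
      if (length(sparse) == 0) sparse <- selmat$final_set[1]
      sets <- list(full = colnames(X), reduced = selmat$final_set,
                   sparse = sparse)
      report$validation <- validate_feature_sets(
        X[split$train, , drop = FALSE], y[split$train],
        X[split$validation, , drop = FALSE], y[split$validation],
        feature_sets = sets, tuned = tuned,
        n_runs = config$validation_runs, seed = seed + 700L)
    }
  }

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write per-stage pipeline artifacts
#'
#' Emits inspectable CSV/JSON artifacts: eigenvalues and explained
#' variance, PCA variable importances, cluster labels and silhouettes,
#' stability metrics, the group-comparison table, the selection matrix
#' (per-method A-memberships plus sum score and final-set marker),
#' the validation cells, and a consolidated JSON report.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(component = seq_along(report$pca$eigenvalues),
               eigenvalue = report$pca$eigenvalues,
               explained_fraction = report$pca$explained_fraction),
    file.path(dir, "pca_eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(variable = names(report$pca$importance),
               importance = as.vector(report$pca$importance),
               set_a = names(report$pca$importance) %in%
                 report$pca$importance_set_a),
    file.path(dir, "pca_importance.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(subject = seq_along(report$clustering$labels),
               cluster = report$clustering$labels),
    file.path(dir, "cluster_labels.csv"), row.names = FALSE)
  utils::write.csv(report$comparison$variables,
                   file.path(dir, "group_comparison.csv"),
                   row.names = FALSE)
  if (!is.null(report$selection)) {
    am <- report$selection$matrix$a_membership
    tab1 <- data.frame(variable = colnames(am),
                       final = colnames(am) %in% report$selection$final_set,
                       sum = as.vector(report$selection$sum_score),
                       t(am) * 1L, check.names = FALSE)
    utils::write.csv(tab1, file.path(dir, "selection_matrix.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$validation))
    utils::write.csv(report$validation$cells,
                     file.path(dir, "validation.csv"), row.names = FALSE)
  summary <- list(
    seed = report$seed,
    n_subjects = report$n_subjects,
    n_missing_cells = report$n_missing_cells,
    n_retained_components = report$pca$n_retained,
    explained_by_retained = report$pca$explained_by_retained,
    best_k = report$clustering$best_k,
    cluster_sizes = report$clustering$cluster_sizes,
    mean_silhouette = report$clustering$mean_silhouette,
    bootstrap_mean_silhouette = report$clustering$stability$mean_silhouette,
    bootstrap_mean_ari = report$clustering$stability$mean_ari,
    final_set = if (!is.null(report$selection)) report$selection$final_set)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Pairwise Pearson correlation report of the olfaction variables
#'
#' Correlation coefficient and p-value for every pair of olfaction
#' variables of a (complete) cohort table, in long format.
#'
#' @param table a complete [cohort_table()].
#' @return data.frame with columns var1, var2, r, p.
#' @export
correlation_report <- function(table) {
  Z <- olfaction_matrix(table)
  vars <- colnames(Z)
  pairs <- utils::combn(vars, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ct <- stats::cor.test(Z[, pairs[1, i]], Z[, pairs[2, i]])
    data.frame(var1 = pairs[1, i], var2 = pairs[2, i],
               r = unname(ct$estimate), p = ct$p.value)
  }))
}
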