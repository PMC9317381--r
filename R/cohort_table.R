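#' Cohort feature table
#'
#' A `cohort_table` is the rectangular subjects x variables store used
#' throughout the pipeline: a numeric matrix (with `NA` marking missing
#' cells), per-variable metadata (role and, once chosen, the power
#' transform applied), and subject identifiers. Olfaction variables are
#' the clustering/selection features; covariates (age, sex, BMI) are kept
#' out of the unsupervised stages but enter group tests and classifiers.
#'
#' @param values numeric matrix, subjects in rows, variables in columns;
#'   column names mandatory and unique. `NA` cells are missing.
#' @param roles named character vector mapping every column to
#'   `"olfaction"` or `"covariate"`.
#' @param subject_ids optional character vector of row identifiers;
#'   defaults to `S001, S002, ...`.
#' @param transforms optional named list of transform records (as produced
#'   by [select_tukey_transform()]), one per already-transformed variable.
#'
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(values, roles, subject_ids = NULL, transforms = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  vn <- colnames(values)
  if (is.null(vn) || anyDuplicated(vn))
    stop("'values' must have unique column names")
  if (!all(vn %in% names(roles)))
    stop("every column needs a role; missing: ",
         paste(setdiff(vn, names(roles)), collapse = ", "))
  roles <- roles[vn]
  if (!all(roles %in% c("olfaction", "covariate")))
    stop("roles must be 'olfaction' or 'covariate'")
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length must match number of rows")
  rownames(values) <- subject_ids
  structure(
    list(values = values, roles = roles,
         subject_ids = as.character(subject_ids), transforms = transforms),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects x %d variables (%d olfaction, %d covariate)\n",
              nrow(x$values), ncol(x$values),
              sum(x$roles == "olfaction"), sum(x$roles == "covariate")))
  cat(sprintf("missing cells: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Names of the olfaction variables of a cohort table
#' @param table a [cohort_table()].
#' @return character vector of column names.
#' @export
olfaction_vars <- function(table) {
  names(table$roles)[table$roles == "olfaction"]
}

#' Names of the covariate variables of a cohort table
#' @param table a [cohort_table()].
#' @return character vector of column names.
#' @export
covariate_vars <- function(table) {
  names(table$roles)[table$roles == "covariate"]
}

#' Extract the olfaction block as a numeric matrix
#' @param table a [cohort_table()].
#' @return numeric matrix restricted to olfaction columns.
#' @export
olfaction_matrix <- function(table) {
  table$values[, olfaction_vars(table), drop = FALSE]
}

#' Write a cohort table as CSV plus a YAML variable-role sidecar
#'
#' Missing cells are written as empty strings; the sidecar records each
#' variable's role and any transform already applied so a run is auditable
#' from its on-disk artifacts. `read_cohort_csv()` round-trips the result,
#' including the missingness mask.
#'
#' @param table a [cohort_table()].
#' @param path CSV file path.
#' @param sidecar YAML file path; defaults to `path` with a `.yml` suffix.
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(table, path, sidecar = paste0(path, ".yml")) {
  df <- data.frame(subject_id = table$subject_ids, table$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(variables = lapply(colnames(table$values), function(v) {
    rec <- list(name = v, role = unname(table$roles[[v]]))
    tr <- table$transforms[[v]]
    if (!is.null(tr))
      rec$transform <- list(power = tr$power, offset = tr$offset)
    rec
  }))
  yaml::write_yaml(meta, sidecar)
  invisible(c(csv = path, sidecar = sidecar))
}

#' Read a cohort table from CSV plus its YAML sidecar
#'
#' @param path CSV file path with a `subject_id` column and one numeric
#'   column per variable; empty cells are read as missing.
#' @param sidecar YAML sidecar path mapping every variable to a role.
#' @return a [cohort_table()].
#' @export
read_cohort_csv <- function(path, sidecar = paste0(path, ".yml")) {
  if (!file.exists(sidecar))
    stop("sidecar file not found: ", sidecar)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  if (anyDuplicated(names(df)))
    stop("duplicate column names in ", path)
  if (!"subject_id" %in% names(df))
    stop("cohort CSV must contain a 'subject_id' column")
  ids <- as.character(df$subject_id)
  df$subject_id <- NULL
  meta <- yaml::read_yaml(sidecar)
  roles <- vapply(meta$variables, function(v) v$role, character(1))
  names(roles) <- vapply(meta$variables, function(v) v$name, character(1))
  unmapped <- setdiff(names(df), names(roles))
  if (length(unmapped))
    stop("sidecar does not map column(s): ", paste(unmapped, collapse = ", "))
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  transforms <- list()
  for (v in meta$variables)
    if (!is.null(v$transform))
      transforms[[v$name]] <- list(power = v$transform$power,
                                   offset = v$transform$offset)
  cohort_table(as.matrix(df), roles, ids, transforms)
}
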