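#' Variable names of the emulated olfactory battery
#'
#' The 15 olfaction variables produced by the extended test battery
#' (Sniffin' Sticks subtests, odor-distance test per nostril, two
#' dilution-sorting tasks with raw and time-corrected scores,
#' lateralization, enantiomer discrimination, post-adaptation threshold,
#' and the three questionnaire subscales), plus the age/sex/BMI
#' covariates.
#'
#' @return list with `olfaction` and `covariates` character vectors.
#' @export
olfactory_battery_vars <- function() {
  list(
    olfaction = c(
      "olf_threshold", "olf_discrimination", "olf_identification",
      "distance_right", "distance_left",
      "score_pea", "score_pea_time", "score_eug", "score_eug_time",
      "lateralization_correct", "enantiomer_correct",
      "threshold_post_adaptation",
      "importance_association", "importance_application",
      "importance_consequence"),
    covariates = c("age", "sex", "bmi"))
}

default_effect_sizes <- function() {
  # signed Cohen's d on the latent scale, cluster 1 minus cluster 0;
  # cluster 1 is the poorer-performing subgroup, so sorting errors rise
  # while subtest scores, perception distances and rated importance drop
  c(olf_threshold = -0.35, olf_discrimination = -0.40,
    olf_identification = -0.45,
    distance_right = -0.70, distance_left = -0.70,
    score_pea = 1.10, score_pea_time = 1.30,
    score_eug = 1.20, score_eug_time = 1.00,
    lateralization_correct = -0.10, enantiomer_correct = -0.20,
    threshold_post_adaptation = -0.20,
    importance_association = -0.15, importance_application = -0.80,
    importance_consequence = -0.15)
}

default_marginal_family <- function() {
  vars <- olfactory_battery_vars()$olfaction
  fam <- stats::setNames(rep("normal", length(vars)), vars)
  fam[c("olf_threshold", "threshold_post_adaptation",
        "distance_right", "distance_left")] <- "lognormal"
  fam
}

# observed-scale location/scale per variable: (meanlog, sdlog) for
# lognormal marginals, (mean, sd) for normal ones
marginal_params <- function() {
  list(
    olf_threshold = c(log(8), 0.30),
    olf_discrimination = c(12, 2.2),
    olf_identification = c(12.5, 2.0),
    distance_right = c(log(9), 0.55),
    distance_left = c(log(9), 0.55),
    score_pea = c(4.0, 2.2),
    score_pea_time = c(0.060, 0.025),
    score_eug = c(4.5, 2.3),
    score_eug_time = c(0.065, 0.028),
    lateralization_correct = c(32, 4),
    enantiomer_correct = c(2.4, 0.9),
    threshold_post_adaptation = c(log(6), 0.35),
    importance_association = c(11, 3),
    importance_application = c(11, 3),
    importance_consequence = c(11, 3))
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' planted two-cluster split, per-variable between-cluster effect sizes
#' (Cohen's d on the latent Gaussian scale), within-block correlations for
#' the questionnaire, odor-distance and non-threshold Sniffin' blocks,
#' the fraction of olfaction cells masked missing-completely-at-random,
#' and each variable's marginal family.
#'
#' @param n_subjects cohort size (default 135).
#' @param cluster_sizes sizes of the planted clusters; must sum to
#'   `n_subjects` (default 80/55).
#' @param effect_sizes named numeric vector of latent Cohen's d values per
#'   olfaction variable; defaults concentrate the signal in the four
#'   sorting-task variables (|d| 1.0-1.3), with importance-of-application
#'   0.8, odor distances 0.6-0.7, Sniffin' subtests 0.35-0.45 and the rest
#'   at 0.3 or below.
#' @param block_correlations named vector of within-block latent Pearson r
#'   for `questionnaire`, `peanut` and `sniffin` blocks (default 0.5 each).
#' @param missing_fraction fraction of olfaction cells masked MCAR
#'   (default 0.04); must stay below the pipeline's 0.2 retention cutoff.
#' @param marginal_family named character vector, `"normal"` or
#'   `"lognormal"` per olfaction variable.
#' @param seed integer seed making generation reproducible.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 135,
                             cluster_sizes = c(80, 55),
                             effect_sizes = default_effect_sizes(),
                             block_correlations = c(questionnaire = 0.5,
                                                    peanut = 0.5,
                                                    sniffin = 0.5),
                             missing_fraction = 0.04,
                             marginal_family = default_marginal_family(),
                             seed = 1L) {
  if (sum(cluster_sizes) != n_subjects)
    stop("cluster_sizes must sum to n_subjects")
  if (any(!is.finite(effect_sizes)))
    stop("effect sizes must be finite")
  if (missing_fraction < 0 || missing_fraction >= 0.2)
    stop("missing_fraction must lie in [0, 0.2): at 0.2 the retention rule would drop data by construction")
  if (any(abs(block_correlations) >= 1))
    stop("block correlations must lie in (-1, 1)")
  vars <- olfactory_battery_vars()$olfaction
  es <- stats::setNames(rep(0, length(vars)), vars)
  es[names(effect_sizes)] <- effect_sizes
  fam <- default_marginal_family()
  fam[names(marginal_family)] <- marginal_family
  structure(list(n_subjects = n_subjects, cluster_sizes = cluster_sizes,
                 effect_sizes = es, block_correlations = block_correlations,
                 missing_fraction = missing_fraction, marginal_family = fam,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

latent_correlation <- function(config) {
  vars <- olfactory_battery_vars()$olfaction
  p <- length(vars)
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  blocks <- list(
    questionnaire = c("importance_association", "importance_application",
                      "importance_consequence"),
    peanut = c("distance_right", "distance_left"),
    sniffin = c("olf_discrimination", "olf_identification"))
  for (b in names(blocks)) {
    idx <- blocks[[b]]
    r <- config$block_correlations[[b]]
    R[idx, idx] <- r
    diag(R[idx, idx]) <- 1
  }
  # a sorting score and its time-corrected counterpart derive from the
  # same sorting performance and are strongly correlated in real data
  R["score_pea", "score_pea_time"] <- R["score_pea_time", "score_pea"] <- 0.7
  R["score_eug", "score_eug_time"] <- R["score_eug_time", "score_eug"] <- 0.7
  R
}

#' Generate a synthetic olfactory cohort with planted cluster structure
#'
#' Subjects are drawn from a latent multivariate Gaussian with unit
#' variances, block correlations, and a between-cluster mean shift equal
#' to the configured Cohen's d per variable (so effect sizes stay
#' interpretable before marginal transforms and missingness). Lognormal
#' marginals are obtained by exponentiating the latent scale, yielding the
#' positive right-skewed thresholds and distances real batteries show.
#' Covariates: age and BMI get small cluster shifts; sex is Bernoulli with
#' cluster-dependent probability of being female (0.70 vs 0.49). The
#' requested fraction of olfaction cells (only) is masked MCAR.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (a [cohort_table()]) and `labels`
#'   (integer 0/1 cluster membership per subject).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  vars <- olfactory_battery_vars()$olfaction
  p <- length(vars)
  n <- config$n_subjects
  labels <- rep(seq_along(config$cluster_sizes) - 1L, config$cluster_sizes)

  R <- latent_correlation(config)
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  colnames(Z) <- vars
  # planted mean shift: half the effect on each side keeps pooled SD ~ 1
  shift <- outer(labels - 0.5, config$effect_sizes[vars])
  Z <- Z + shift

  pars <- marginal_params()
  X <- Z
  for (v in vars) {
    mp <- pars[[v]]
    if (config$marginal_family[[v]] == "lognormal")
      X[, v] <- exp(mp[1] + mp[2] * Z[, v])
    else
      X[, v] <- mp[1] + mp[2] * Z[, v]
  }

  age <- ifelse(labels == 0, 28 + 9.7 * stats::rnorm(n),
                34 + 13.2 * stats::rnorm(n))
  age <- pmax(18, age)
  sex <- stats::rbinom(n, 1, ifelse(labels == 0, 0.70, 0.49))  # 1 = female
  bmi <- exp(log(22.8) + 0.16 * (stats::rnorm(n) + 0.1 * labels))
  X <- cbind(X, age = age, sex = sex, bmi = bmi)

  n_mask <- round(config$missing_fraction * n * p)
  if (n_mask > 0) {
    cells <- sample(n * p, n_mask)
    for (cell in cells)
      X[(cell - 1) %% n + 1, (cell - 1) %/% n + 1] <- NA
  }

  roles <- stats::setNames(c(rep("olfaction", p), rep("covariate", 3)),
                           colnames(X))
  tab <- cohort_table(X, roles)
  names(labels) <- tab$subject_ids  # survives later case filtering
  list(table = tab, labels = labels)
}

#' Configuration of the behavioral sorting-task simulator
#'
#' @param n_items number of dilutions to sort (fixed at 5 for the task).
#' @param dispersion nonnegative Mallows-type concentration per cluster
#'   (0 = every subject sorts perfectly; larger values yield noisier
#'   permutations and thus larger expected footrule scores).
#' @param time_meanlog,time_sdlog lognormal parameters of the task
#'   duration in seconds.
#' @param seed integer seed.
#' @return object of class `sorting_sim_config`.
#' @export
sorting_sim_config <- function(n_items = 5L, dispersion = c(0.2, 0.6),
                               time_meanlog = log(60), time_sdlog = 0.4,
                               seed = 1L) {
  if (any(dispersion < 0)) stop("dispersion must be nonnegative")
  if (time_sdlog < 0) stop("time_sdlog must be nonnegative")
  structure(list(n_items = as.integer(n_items), dispersion = dispersion,
                 time_meanlog = time_meanlog, time_sdlog = time_sdlog,
                 seed = as.integer(seed)),
            class = "sorting_sim_config")
}

# Mallows permutation by repeated insertion: item i goes to position j <= i
# with weight dispersion^(i - j); dispersion 0 gives the identity.
rmallows <- function(n_items, dispersion) {
  ord <- integer(0)
  for (i in seq_len(n_items)) {
    w <- dispersion^(i - seq_len(i))
    w[i] <- 1  # 0^0: keep the in-place insertion possible at dispersion 0
    j <- sample.int(i, 1, prob = w)
    ord <- append(ord, i, after = j - 1)
  }
  ord
}

#' Simulate behavioral responses to the dilution-sorting task
#'
#' Draws one permutation of the dilution ranks per subject from a Mallows
#' model centered on the correct ascending order (sampled exactly by
#' repeated insertion), with a per-cluster dispersion, plus a lognormal
#' task duration.
#'
#' @param n_per_cluster integer vector of subjects per cluster.
#' @param config a [sorting_sim_config()]; `dispersion` must have one
#'   entry per cluster.
#' @return list of responses, each a list with `assigned_order`
#'   (permutation of `1..n_items`), `duration` (seconds) and `cluster`.
#' @export
generate_sorting_responses <- function(n_per_cluster,
                                       config = sorting_sim_config()) {
  stopifnot(inherits(config, "sorting_sim_config"))
  if (length(config$dispersion) == 1)
    config$dispersion <- rep(config$dispersion, length(n_per_cluster))
  if (length(config$dispersion) != length(n_per_cluster))
    stop("one dispersion per cluster required")
  set.seed(config$seed)
  out <- list()
  for (cl in seq_along(n_per_cluster)) {
    for (i in seq_len(n_per_cluster[cl])) {
      ord <- rmallows(config$n_items, config$dispersion[cl])
      dur <- stats::rlnorm(1, config$time_meanlog, config$time_sdlog)
      out[[length(out) + 1]] <- list(assigned_order = ord, duration = dur,
                                     cluster = cl - 1L)
    }
  }
  out
}
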