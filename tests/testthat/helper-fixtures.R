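# shared helpers: small deterministic fixtures and brute-force oracles

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# brute-force two-sided Mann-Whitney p: enumerate every assignment of the
# pooled values to the two groups and compare tail probabilities of U
brute_force_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  combos <- utils::combn(n1 + n2, n1)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- apply(combos, 2, u_of)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p.value = min(1, p))
}

# pair-counting adjusted Rand oracle: classify every subject pair as
# together/apart in each partition and apply the 2x2 pair-count formula
brute_force_ari <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# tiny two-blob dataset with controllable separation (in within-blob SDs)
make_blobs <- function(n_per = 30, separation = 10, dim = 2, seed = 1,
                       k = 2) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k) - 1, function(i)
    matrix(stats::rnorm(n_per * dim), n_per, dim) +
      separation * i))
  list(x = X, labels = rep(seq_len(k) - 1L, each = n_per))
}

# quick cohort fixture shared by several files
small_cohort <- function(seed = 1) {
  gen <- generate_cohort(synthetic_config(seed = seed))
  pre <- preprocess_cohort(gen$table, seed = seed)
  list(gen = gen, pre = pre, ztab = z_standardize(pre))
}

default_tuned <- function() {
  list(svm = list(cost = 1),
       rf = list(num_trees = 200, max_depth = 10),
       logreg = list(alpha = 0, lambda = 0.01))
}
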