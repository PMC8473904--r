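# Independent oracles and small fixture builders shared across tests.

# brute-force two-pass Fisher score: loops, no matrix algebra, sample sd
oracle_fisher <- function(mat, labels) {
  classes <- sort(unique(labels))
  scores <- numeric(ncol(mat))
  for (i in seq_len(ncol(mat))) {
    mu_i <- mean(mat[, i])
    num <- 0
    den <- 0
    for (cl in classes) {
      v <- mat[labels == cl, i]
      num <- num + length(v) * (mean(v) - mu_i)^2
      den <- den + length(v) * stats::var(v)
    }
    scores[i] <- if (den > 0) num / den else if (num > 0) Inf else 0
  }
  names(scores) <- colnames(mat)
  scores
}

# exhaustive minimum WCSS over all partitions of <= 8 points into k
# non-empty clusters (enumerates k^n label vectors)
oracle_min_wcss <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 8, k <= 3)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    a <- grid[i, ]
    if (length(unique(a)) < k) next
    w <- 0
    for (j in unique(a)) {
      sub <- x[a == j, , drop = FALSE]
      w <- w + sum(sweep(sub, 2L, colMeans(sub))^2)
    }
    if (w < best) best <- w
  }
  best
}

# plain-loop KNN oracle: mean accuracy over k values for explicit
# train/test index sets; ties broken as documented (neighbour order by
# distance then train position, vote by lowest class)
oracle_knn_accuracy <- function(mat, labels, train_idx, test_idx, k_values) {
  classes <- sort(unique(labels))
  accs <- numeric(length(k_values))
  for (ki in seq_along(k_values)) {
    k <- min(k_values[ki], length(train_idx))
    correct <- 0
    for (te in test_idx) {
      d <- sapply(train_idx, function(tr) sum((mat[te, ] - mat[tr, ])^2))
      ord <- order(d, seq_along(d))
      neigh <- labels[train_idx][ord[seq_len(k)]]
      votes <- sapply(classes, function(cl) sum(neigh == cl))
      pred <- classes[which.max(votes)]
      if (pred == labels[te]) correct <- correct + 1
    }
    accs[ki] <- correct / length(test_idx)
  }
  mean(accs)
}

# labelled random matrix with dimnames
rand_mat <- function(n, p, seed = 1, mean = 0, sd = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * p, mean, sd), n, p,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("g%03d", seq_len(p))))
    m
  })
}

# quick small-scale pipeline config used across tests
quick_config <- function(...) {
  pipeline_config(n_filter_fisher = 30, n_filter_rfe = 30,
                  sffs_subset_size = 5, n_sffs_trials = 8,
                  panel_size = 10, n_cv_repeats = 2, ...)
}

# blockless planted fixture
planted_fixture <- function(seed, n_samples = 60, n_genes = 200,
                            effect_size = 3, n_informative = 15, ...) {
  generate_expression(synthetic_spec(
    n_samples = n_samples, n_genes = n_genes, n_informative = n_informative,
    effect_size = effect_size, n_correlated_blocks = 0, block_size = 0,
    seed = seed, ...))
}
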