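test_that("knn objective is 1 for point-mass classes and matches the brute-force oracle", {
  cfg <- pipeline_config(master_seed = 1)
  x <- matrix(rep(c(0, 50), each = 10), 20, 1,
              dimnames = list(sprintf("s%02d", 1:20), "g1"))
  x <- x + withr::with_seed(1, matrix(rnorm(20, sd = 1e-3), 20, 1))
  labels <- rep(c("A", "B"), each = 10)
  expect_equal(knn_objective(x, labels, 77, cfg, warn_small_class = FALSE), 1)

  # fixed 12-sample, 2-gene instance vs a plain-loop oracle over many splits
  mat <- rand_mat(12, 2, seed = 55)
  labels12 <- rep(c("A", "B"), each = 6)
  for (ss in c(3, 19, 101)) {
    test_idx <- withr::with_seed(ss, {
      idx <- integer(0)
      for (cl in c("A", "B")) {
        w <- which(labels12 == cl)
        idx <- c(idx, w[sample.int(length(w), round(0.3 * length(w)))])
      }
      sort(idx)
    })
    oracle <- oracle_knn_accuracy(mat, labels12, setdiff(1:12, test_idx),
                                  test_idx, 3:9)
    expect_equal(knn_objective(mat, labels12, ss, cfg,
                               warn_small_class = FALSE),
                 oracle, tolerance = 1e-12)
  }
})

test_that("knn objective sits at chance level for permuted labels", {
  cfg <- pipeline_config(master_seed = 2)
  mat <- rand_mat(60, 5, seed = 66)
  # a fresh label permutation per split, so dataset-level chance correlation
  # between one fixed labelling and the noise matrix averages out
  vals <- vapply(1:200, function(i) {
    labels <- withr::with_seed(derive_seed(cfg, "chance_labels", i),
                               sample(rep(c("a", "b", "c"), each = 20)))
    knn_objective(mat, labels, derive_seed(cfg, "chance", i), cfg,
                  warn_small_class = FALSE)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1 / 3), 0.05)
})

test_that("knn objective is invariant under uniform scaling of the feature space", {
  cfg <- pipeline_config(master_seed = 3)
  sim <- planted_fixture(seed = 5, n_samples = 40, n_genes = 10,
                         n_informative = 5, effect_size = 1.5)
  v1 <- knn_objective(sim$matrix, sim$truth$labels, 11, cfg,
                      warn_small_class = FALSE)
  v2 <- knn_objective(sim$matrix * 7.3, sim$truth$labels, 11, cfg,
                      warn_small_class = FALSE)
  expect_identical(v1, v2)
})

test_that("sffs returns the full pool when asked for it and seeds a perfect gene first", {
  cfg <- pipeline_config(master_seed = 4)
  sim <- planted_fixture(seed = 6, n_samples = 40, n_genes = 8,
                         n_informative = 4, effect_size = 1.5)
  res <- sffs_search(sim$matrix, sim$truth$labels, 8, 13, cfg)
  expect_setequal(res$selected_subset, colnames(sim$matrix))

  x <- cbind(perfect = rep(c(0, 100, 200), each = 10) +
               withr::with_seed(2, rnorm(30, sd = 0.01)),
             rand_mat(30, 4, seed = 7))
  rownames(x) <- sprintf("s%02d", 1:30)
  labels <- rep(c("a", "b", "c"), each = 10)
  res2 <- sffs_search(x, labels, 2, 21, cfg)
  expect_equal(res2$objective_trajectory[1], 1)
  expect_true("perfect" %in% res2$selected_subset)
})

test_that("a trial's objective value re-evaluates exactly via knn_objective", {
  cfg <- pipeline_config(master_seed = 5)
  sim <- planted_fixture(seed = 8, n_samples = 40, n_genes = 30,
                         n_informative = 8, effect_size = 1.5)
  res <- sffs_search(sim$matrix, sim$truth$labels, 5, 31, cfg)
  direct <- knn_objective(sim$matrix[, res$selected_subset, drop = FALSE],
                          sim$truth$labels, 31, cfg,
                          warn_small_class = FALSE)
  expect_equal(res$objective_value, direct, tolerance = 1e-12)
})

test_that("randomized trials compose, are deterministic, and order-independent", {
  cfg <- pipeline_config(sffs_subset_size = 4, n_sffs_trials = 3,
                         master_seed = 6)
  sim <- planted_fixture(seed = 9, n_samples = 40, n_genes = 20,
                         n_informative = 6, effect_size = 2)
  one <- run_randomized_trials(sim$matrix, sim$truth$labels, cfg,
                               n_trials = 1)
  direct <- sffs_search(sim$matrix, sim$truth$labels, 4,
                        derive_seed(cfg, "sffs", 1), cfg)
  expect_identical(one[[1]]$selected_subset, direct$selected_subset)
  expect_identical(one[[1]]$objective_value, direct$objective_value)

  t1 <- run_randomized_trials(sim$matrix, sim$truth$labels, cfg)
  t2 <- run_randomized_trials(sim$matrix, sim$truth$labels, cfg)
  expect_identical(lapply(t1, `[[`, "selected_subset"),
                   lapply(t2, `[[`, "selected_subset"))
  # order independence: trial 3 run alone equals trial 3 of the batch
  alone <- sffs_search(sim$matrix, sim$truth$labels, 4,
                       derive_seed(cfg, "sffs", 3), cfg)
  expect_identical(t1[[3]]$selected_subset, alone$selected_subset)
})

test_that("frequency consolidation counts, conserves and ranks", {
  mk_trial <- function(genes) structure(list(selected_subset = genes),
                                        class = "sffs_trial")
  same <- replicate(5, mk_trial(c("a", "b", "c")), simplify = FALSE)
  out <- consolidate_frequencies(same, 3)
  expect_setequal(out$panel, c("a", "b", "c"))
  expect_true(all(out$frequency_table$count == 5))

  tr <- list(mk_trial(c("a", "b")), mk_trial(c("a", "c")),
             mk_trial(c("a", "d")))
  out2 <- consolidate_frequencies(tr, 1)
  expect_identical(out2$panel, "a")
  expect_identical(out2$frequency_table$count[1], 3L)
  expect_identical(sum(out2$frequency_table$count), 3L * 2L)

  expect_error(consolidate_frequencies(tr, 10), "panel_size exceeds")
  expect_error(consolidate_frequencies(list(), 1), ">= 1 trial")
})

test_that("frequency conservation holds on real trials", {
  cfg <- pipeline_config(sffs_subset_size = 4, n_sffs_trials = 6,
                         master_seed = 7)
  sim <- planted_fixture(seed = 10, n_samples = 40, n_genes = 20,
                         n_informative = 6, effect_size = 2)
  trials <- run_randomized_trials(sim$matrix, sim$truth$labels, cfg)
  out <- consolidate_frequencies(trials, 4)
  expect_identical(sum(out$frequency_table$count), 6L * 4L)
  expect_true(all(out$frequency_table$count >= 0 &
                    out$frequency_table$count <= 6L))
})

test_that("the full pipeline runs and persists coherent artifacts", {
  cfg <- quick_config(master_seed = 8)
  sim <- planted_fixture(seed = 11, n_samples = 40, n_genes = 80,
                         n_informative = 10, effect_size = 3)
  out_dir <- withr::local_tempdir()
  res <- run_feature_selection_pipeline(sim$matrix, sim$truth$labels, cfg,
                                        out_dir = out_dir)
  expect_length(res$pool, length(unique(res$pool)))
  expect_length(res$panel, 10L)
  expect_identical(sum(res$frequency_table$count), 8L * 5L)
  expect_true(all(file.exists(file.path(out_dir, c(
    "ranking_fisher.tsv", "ranking_svm_rfe_cbr.tsv", "pool.tsv",
    "trial_subsets.tsv", "frequency.tsv", "panel.tsv", "manifest.json")))))
  freq <- read.delim(file.path(out_dir, "frequency.tsv"))
  expect_identical(sum(freq$count), 40L)
  # most of the planted signal survives to the panel at this scale
  expect_gte(sum(res$panel %in% sim$truth$informative_gene_ids), 7L)
})
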