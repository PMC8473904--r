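test_that("re-clustering on all genes reproduces the clustering's own labels", {
  sim <- planted_fixture(seed = 13, n_samples = 40, n_genes = 60)
  cfg <- pipeline_config(master_seed = 9)
  base <- kmeanspp_fit(sim$matrix, 3, cfg$n_kmeans_restarts,
                       seed = derive_seed(cfg, "revalidate", 0L))
  rv <- revalidate_clustering(sim$matrix, base$labels, cfg)
  expect_equal(rv$agreement, 1)
  expect_s3_class(rv$curve, "wcss_curve")
})

test_that("the panel sharpens the elbow relative to the full matrix", {
  cfg <- pipeline_config(master_seed = 10)
  for (seed in 1:3) {
    sim <- planted_fixture(seed, n_samples = 60, n_genes = 300)
    full_curve <- wcss_curve(sim$matrix, 1, 8, 10, seed = seed)
    rv <- revalidate_clustering(sim$matrix[, sim$truth$informative_gene_ids],
                                sim$truth$labels, cfg, k_max = 8)
    full_score <- detect_elbow(full_curve)$curvature_scores[["3"]]
    panel_score <- detect_elbow(rv$curve)$curvature_scores[["3"]]
    expect_gt(panel_score, full_score)
    expect_gte(rv$agreement, 0.95)
  }
})

test_that("the classifier suite is perfect on widely separated clusters", {
  sim <- planted_fixture(seed = 14, n_samples = 60, n_genes = 15,
                         n_informative = 15, effect_size = 10)
  cfg <- pipeline_config(n_cv_repeats = 2, master_seed = 11)
  rep <- suppressWarnings(
    crossvalidate_suite(sim$matrix, sim$truth$labels, cfg))
  expect_identical(nrow(rep), 6L)
  expect_true(all(rep$average > 99.9))
  expect_true(all(as.matrix(rep[, c("1", "2", "3")]) >= 0 &
                    as.matrix(rep[, c("1", "2", "3")]) <= 100))
  # macro average equals the mean of the per-cluster values
  expect_equal(rep$average, rowMeans(rep[, c("1", "2", "3")]),
               tolerance = 1e-9)
})

test_that("suite results are invariant to sample shuffling", {
  sim <- planted_fixture(seed = 15, n_samples = 40, n_genes = 10,
                         n_informative = 10)
  cfg <- pipeline_config(n_cv_repeats = 1, master_seed = 12)
  r1 <- suppressWarnings(crossvalidate_suite(
    sim$matrix, sim$truth$labels, cfg, classifiers = c("knn", "naive_bayes")))
  perm <- withr::with_seed(4, sample(40))
  r2 <- suppressWarnings(crossvalidate_suite(
    sim$matrix[perm, ], sim$truth$labels[perm], cfg,
    classifiers = c("knn", "naive_bayes")))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("shuffled labels drop every family to chance level", {
  mat <- rand_mat(45, 8, seed = 71, mean = 7)
  labels <- withr::with_seed(5, sample(rep(c("a", "b", "c"), each = 15)))
  cfg <- pipeline_config(n_cv_folds = 5, n_cv_repeats = 5, master_seed = 13)
  rep <- suppressWarnings(crossvalidate_suite(mat, labels, cfg))
  expect_true(all(abs(rep$average - 100 / 3) < 10 * 3))
  expect_true(all(rep$average < 60))
})

test_that("a clean two-class gap yields the midpoint rule pair", {
  mat <- matrix(c(1, 2, 8, 9), 4, 1,
                dimnames = list(paste0("s", 1:4), "GENE1"))
  tr <- train_decision_tree(mat, c("A", "A", "B", "B"))
  expect_length(tr$rules, 2L)
  tab <- rules_table(tr$rules)
  expect_setequal(tab$cluster, c("A", "B"))
  thr <- tr$rules[[1]]$predicates$threshold
  expect_equal(thr, 5)
  expect_identical(predict_rules(tr$rules, mat), c("A", "A", "B", "B"))
})

test_that("extracted rules reproduce the tree's predictions exactly", {
  for (seed in 1:20) {
    n <- 24 + (seed %% 3) * 8
    mat <- rand_mat(n, 5, seed = 100 + seed, mean = 8)
    labels <- withr::with_seed(200 + seed,
                               sample(c("c1", "c2", "c3"), n, replace = TRUE))
    if (min(table(labels)) < 2) next
    tr <- train_decision_tree(mat, labels)
    tree_pred <- as.character(predict(tr$model,
                                      data.frame(mat, check.names = FALSE),
                                      type = "class"))
    expect_identical(predict_rules(tr$rules, mat), tree_pred)
    # leaf property: exactly one rule fires per sample (predict_rules errors
    # otherwise), and rules cover fresh data from the same range too
    fresh <- rand_mat(n, 5, seed = 300 + seed, mean = 8)
    expect_identical(predict_rules(tr$rules, fresh),
                     as.character(predict(tr$model,
                                          data.frame(fresh,
                                                     check.names = FALSE),
                                          type = "class")))
  }
})

test_that("drug summaries report n/mean/sd per (cluster, drug) with missing handled", {
  drugs <- matrix(c(1, 2, 3, NA, NA, NA), 3, 2,
                  dimnames = list(c("s1", "s2", "s3"), c("dA", "dB")))
  labels <- stats::setNames(rep(1L, 3), c("s1", "s2", "s3"))
  summ <- drug_summary(drugs, labels)
  dA <- summ[summ$drug == "dA", ]
  expect_identical(dA$n, 3L)
  expect_equal(dA$mean, 2)
  expect_equal(dA$sd, 1)
  dB <- summ[summ$drug == "dB", ]
  expect_identical(dB$n, 0L)
  expect_true(is.na(dB$mean) && is.na(dB$sd))

  expect_error(drug_summary(drugs, labels, character(0)), "empty drug")
  expect_error(drug_summary(drugs, labels, "nope"), "unknown drug")
})

test_that("per-cluster sample sizes sum to each drug's non-missing count", {
  sim <- planted_fixture(seed = 16, n_samples = 50, n_genes = 20)
  means <- cbind(d1 = c(3, 2.5, 1.5), d2 = c(4, 3.5, 2))
  dr <- generate_drug_response(sim$truth, means, response_sd = 1,
                               missing_fraction = 0.25, seed = 17)
  summ <- drug_summary(dr, sim$truth$labels)
  for (d in colnames(dr)) {
    expect_identical(sum(summ$n[summ$drug == d]),
                     sum(!is.na(dr[, d])))
  }
})

test_that("the emulated two-drug study recovers its cluster means and ordering", {
  # cluster means and sizes follow the published two-MEK-inhibitor summary;
  # recovery tolerance is statistical (3 * sd / sqrt(n))
  spec <- synthetic_spec(n_samples = 33, n_genes = 20, n_clusters = 3,
                         cluster_proportions = c(13, 16, 4) / 33,
                         n_informative = 6, n_correlated_blocks = 0,
                         block_size = 0, seed = 18)
  truth <- generate_expression(spec)$truth
  expect_identical(truth$cluster_sizes, c(13L, 16L, 4L))
  means <- cbind(AZD = c(2.9335, 2.6125, 1.5511),
                 PD = c(4.1911, 3.7534, 2.1695))
  sds <- c(1.1, 1.5)
  dr <- generate_drug_response(truth, means, response_sd = 1.1, seed = 19)
  summ <- drug_summary(dr, truth$labels)
  for (cl in 1:3) {
    for (j in 1:2) {
      got <- summ$mean[summ$cluster == cl & summ$drug == colnames(means)[j]]
      n <- truth$cluster_sizes[cl]
      expect_lt(abs(got - means[cl, j]), 3 * 1.1 / sqrt(n))
    }
  }
  # monotone-decreasing means across clusters hold in most replicates
  mono <- vapply(1:40, function(s) {
    d <- generate_drug_response(truth, means, response_sd = 1.1, seed = s)
    all(attr(drug_summary(d, truth$labels), "monotone_decreasing"))
  }, logical(1))
  expect_gte(mean(mono), 0.5)
})
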