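## SFFS wrapped around a KNN test-split objective, randomized trials, and
## frequency consolidation into the final panel.

# canonical class coding: classes ordered by sort(unique(labels)),
# "lowest class index" tie-breaks refer to this order
class_codes <- function(labels) {
  classes <- sort(unique(labels))
  list(classes = classes,
       codes = match(labels, classes),
       n = length(classes))
}

# deterministic stratified train/test split; returns test-row indices
make_split <- function(labels, test_fraction, split_seed,
                       warn_small_class = TRUE) {
  cc <- class_codes(labels)
  withr::with_seed(split_seed, {
    test_idx <- integer(0)
    for (cl in cc$classes) {
      idx <- which(labels == cl)
      nt <- round(test_fraction * length(idx))
      if (nt < 2L || length(idx) - nt < 2L)
        stop("class '", cl, "' too small to stratify at test_fraction = ",
             test_fraction, call. = FALSE)
      test_idx <- c(test_idx, idx[sample.int(length(idx), nt)])
    }
    sort(test_idx)
  })
}

check_knn_k <- function(labels, test_idx, k_values, warn = TRUE) {
  smallest <- min(table(labels[-test_idx]))
  if (warn && any(k_values >= smallest))
    warning("knn k value(s) >= smallest training-class size (", smallest,
            "); neighbourhoods will span classes", call. = FALSE)
  invisible(smallest)
}

knn_eval <- function(D, train_codes, test_codes, k_values, n_class) {
  knn_mean_accuracy_cpp(D, as.integer(train_codes), as.integer(test_codes),
                        as.integer(k_values), as.integer(n_class))
}

#' KNN test-split objective for a gene subset
#'
#' Draws one stratified random train/test split at `test_fraction` from
#' `split_seed`, then for each k in `knn_k_values` classifies the test
#' samples by deterministic majority-vote Euclidean KNN (neighbour-distance
#' ties broken by training-sample order, vote ties by lowest class index) and
#' returns the mean of the per-k test accuracies.
#'
#' @param mat_subset Samples x genes matrix restricted to the subset under
#'   evaluation.
#' @param labels Class labels per sample.
#' @param split_seed Integer seed fixing the split.
#' @param config A [pipeline_config()] (uses `test_fraction`,
#'   `knn_k_values`).
#' @param warn_small_class Warn once when some k is at least the smallest
#'   training-class size (the vote then necessarily spans classes).
#' @return Mean accuracy in [0, 1].
#' @export
knn_objective <- function(mat_subset, labels, split_seed,
                          config = pipeline_config(),
                          warn_small_class = TRUE) {
  if (ncol(mat_subset) < 1L) stop("empty gene subset", call. = FALSE)
  cc <- class_codes(labels)
  test_idx <- make_split(labels, config$test_fraction, split_seed)
  check_knn_k(labels, test_idx, config$knn_k_values, warn_small_class)
  xtr <- mat_subset[-test_idx, , drop = FALSE]
  xte <- mat_subset[test_idx, , drop = FALSE]
  D <- sqdist_to_centers(xte, xtr)
  knn_eval(D, cc$codes[-test_idx], cc$codes[test_idx], config$knn_k_values,
           cc$n)
}

#' Sequential floating forward search over a gene pool
#'
#' Classic SFFS with best-subset bookkeeping per size, wrapped around the
#' [knn_objective()] evaluated on a single stratified split fixed by
#' `split_seed`. Each forward step adds the feature maximizing the objective;
#' conditional backward steps then remove the feature whose removal maximizes
#' the objective, accepted only while the result strictly exceeds the best
#' value recorded for the smaller size.
#'
#' The KNN objective is coarse (a handful of test samples times a few k
#' values), so at small sample sizes it plateaus and forward steps tie across
#' many candidates. Ties are resolved by a filter-guided rule standard in
#' hybrid filter/wrapper selection: among objective-tied candidates the one
#' with the higher Fisher score computed on a stratified bootstrap resample
#' of the trial's TRAINING split is added (no test information is used), with
#' any residual tie broken by a random feature order; both are drawn once per
#' trial from `split_seed`. A trial is
#' therefore fully deterministic given its seed, while tie resolution stays
#' independent across trials - a tie order shared by all trials (e.g.
#' lexicographic) would let accuracy plateaus promote the same arbitrary
#' genes in every trial and corrupt the frequency consolidation the
#' randomized trials feed.
#' The search stops when the floating set size equals `target_size` at the
#' end of a forward/backward cycle and returns the best recorded subset of
#' exactly that size. `floating = FALSE` gives plain sequential forward
#' selection (no backward steps) for comparison.
#'
#' @param mat Samples x genes matrix restricted to the candidate pool.
#' @param labels Class labels per sample.
#' @param target_size Requested subset size (<= pool size).
#' @param split_seed Integer seed for the trial's train/test split.
#' @param config A [pipeline_config()].
#' @param floating Perform conditional backward steps (default `TRUE`).
#' @return An object of class `sffs_trial`: `selected_subset` (gene ids,
#'   lexicographic), `objective_value`, `objective_trajectory` (best value
#'   per visited size), `split_seed`, `trial_index` (NA unless run via
#'   [run_randomized_trials()]).
#' @export
sffs_search <- function(mat, labels, target_size, split_seed,
                        config = pipeline_config(), floating = TRUE) {
  validate_expression_matrix(mat)
  pool <- sort(colnames(mat))
  if (target_size < 1L || target_size > length(pool))
    stop("target_size must lie in [1, pool size]", call. = FALSE)
  cc <- class_codes(labels)
  test_idx <- make_split(labels, config$test_fraction, split_seed)
  check_knn_k(labels, test_idx, config$knn_k_values, warn = FALSE)
  train_codes <- cc$codes[-test_idx]
  test_codes <- cc$codes[test_idx]
  n_te <- length(test_idx)
  n_tr <- nrow(mat) - n_te
  # per-gene additive squared-distance contributions: distances over a subset
  # are the sum of its genes' contributions, so candidate evaluation is a
  # vector addition plus one KNN vote pass
  Dflat <- matrix(0, n_te * n_tr, length(pool), dimnames = list(NULL, pool))
  xtr <- mat[-test_idx, pool, drop = FALSE]
  xte <- mat[test_idx, pool, drop = FALSE]
  for (g in seq_along(pool))
    Dflat[, g] <- as.vector(outer(xte[, g], xtr[, g], "-")^2)
  eval_d <- function(dvec) {
    knn_eval(matrix(dvec, n_te, n_tr), train_codes, test_codes,
             config$knn_k_values, cc$n)
  }
  # per-trial tie-breaking: Fisher scores on a stratified bootstrap of the
  # trial's training samples, then a random order. Both are drawn from the
  # trial seed, so a trial is deterministic while tie resolution is
  # decorrelated across trials.
  tie <- withr::with_seed(derive_seed(split_seed, "sffs_ties", 0L), {
    tr_rows <- setdiff(seq_len(nrow(mat)), test_idx)
    boot <- unlist(lapply(sort(unique(labels[tr_rows])), function(cl) {
      w <- tr_rows[labels[tr_rows] == cl]
      w[sample.int(length(w), length(w), replace = TRUE)]
    }))
    bmat <- mat[boot, pool, drop = FALSE]
    rownames(bmat) <- sprintf("b%04d", seq_along(boot))
    bf <- fisher_scores(class_stats(bmat, labels[boot]))
    list(fisher = stats::setNames(bf$score, bf$gene_id)[pool],
         rank = stats::setNames(sample.int(length(pool)), pool))
  })
  fis <- tie$fisher
  fis[!is.finite(fis)] <- max(fis[is.finite(fis)], 0) + 1
  tie_rank <- tie$rank

  cur <- character(0)
  d_cur <- numeric(n_te * n_tr)
  best_val <- rep(-Inf, target_size)
  best_set <- vector("list", target_size)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L * target_size)
      stop("sffs_search failed to terminate", call. = FALSE)
    # forward step
    cand <- setdiff(pool, cur)
    vals <- vapply(cand, function(g) eval_d(d_cur + Dflat[, g]), numeric(1))
    add <- cand[order(-vals, -fis[cand], tie_rank[cand])[1L]]
    cur <- c(cur, add)
    d_cur <- d_cur + Dflat[, add]
    s <- length(cur)
    if (max(vals) > best_val[s]) {
      best_val[s] <- max(vals)
      best_set[[s]] <- sort(cur)
    }
    # conditional backward steps
    if (floating) {
      while (length(cur) > 2L) {
        members <- sort(cur)
        vals_rm <- vapply(members, function(g) eval_d(d_cur - Dflat[, g]),
                          numeric(1))
        drop_g <- members[order(-vals_rm, fis[members],
                                tie_rank[members])[1L]]
        v <- max(vals_rm)
        if (v > best_val[length(cur) - 1L]) {
          cur <- setdiff(cur, drop_g)
          d_cur <- d_cur - Dflat[, drop_g]
          best_val[length(cur)] <- v
          best_set[[length(cur)]] <- sort(cur)
        } else break
      }
    }
    if (length(cur) == target_size) break
  }
  out <- list(
    trial_index = NA_integer_,
    split_seed = split_seed,
    selected_subset = best_set[[target_size]],
    objective_value = best_val[target_size],
    objective_trajectory = best_val
  )
  class(out) <- "sffs_trial"
  out
}

#' Run independently seeded randomized SFFS trials
#'
#' Trial t draws its train/test split from
#' `derive_seed(config, "sffs", t)`, so results are reproducible from the
#' master seed, order-independent, and embarrassingly parallel in principle.
#'
#' @param mat Samples x genes matrix restricted to the candidate pool.
#' @param labels Class labels per sample.
#' @param config A [pipeline_config()]; uses `n_sffs_trials` and
#'   `sffs_subset_size`.
#' @param n_trials,target_size Overrides of the config values.
#' @param progress Print a line every 10 trials.
#' @return List of `sffs_trial` objects with `trial_index` set.
#' @export
run_randomized_trials <- function(mat, labels, config = pipeline_config(),
                                  n_trials = config$n_sffs_trials,
                                  target_size = config$sffs_subset_size,
                                  progress = FALSE) {
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    res <- sffs_search(mat, labels, target_size,
                       split_seed = derive_seed(config, "sffs", t),
                       config = config)
    res$trial_index <- t
    trials[[t]] <- res
    if (progress && t %% 10L == 0L)
      message("sffs trial ", t, "/", n_trials)
  }
  trials
}

#' Consolidate SFFS trials into a frequency table and final panel
#'
#' Counts, for every gene, the number of trials whose selected subset
#' contains it, and returns the `panel_size` most frequent genes. Count ties
#' are broken by higher Fisher score on the full data (when a Fisher ranking
#' is supplied), then by gene id.
#'
#' @param trials List of `sffs_trial` objects.
#' @param panel_size Number of genes in the final panel.
#' @param fisher_ranking Optional `feature_ranking` from [fisher_scores()]
#'   used for tie-breaking.
#' @return List with `frequency_table` (data frame `gene_id`, `count`,
#'   `rank`, covering every gene observed in any trial) and `panel`
#'   (character vector of length `panel_size`).
#' @export
consolidate_frequencies <- function(trials, panel_size,
                                    fisher_ranking = NULL) {
  if (length(trials) < 1L) stop("need >= 1 trial", call. = FALSE)
  counts <- table(unlist(lapply(trials, `[[`, "selected_subset")))
  gene_id <- names(counts)
  if (panel_size > length(gene_id))
    stop("panel_size exceeds the number of distinct genes observed",
         call. = FALSE)
  fscore <- rep(0, length(gene_id))
  if (!is.null(fisher_ranking))
    fscore <- fisher_ranking$score[match(gene_id, fisher_ranking$gene_id)]
  fscore[is.na(fscore)] <- -Inf
  ord <- order(-as.integer(counts), -fscore, gene_id)
  tab <- data.frame(gene_id = gene_id[ord],
                    count = as.integer(counts)[ord],
                    rank = seq_along(gene_id),
                    stringsAsFactors = FALSE)
  list(frequency_table = tab, panel = tab$gene_id[seq_len(panel_size)])
}

#' Full feature-selection pipeline: filters, pooling, trials, panel
#'
#' Executes the whole selection cascade on a labelled expression matrix:
#' (1) Fisher-score filter keeping the top `n_filter_fisher` genes;
#' (2) SVM-RFE+CBR keeping the top `n_filter_rfe`;
#' (3) pooling of the two lists with deduplication;
#' (4) `n_sffs_trials` randomized SFFS/KNN trials on the pooled matrix, each
#'     returning a subset of `sffs_subset_size` genes;
#' (5) frequency consolidation into the final `panel_size`-gene panel.
#'
#' @param mat Samples x genes matrix.
#' @param labels Cluster labels per sample (typically from
#'   [kmeanspp_fit()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, every intermediate
#'   artifact (rankings, pool, per-trial subsets, frequency table, panel,
#'   manifest) is written as TSV/JSON.
#' @param progress Log stage progress.
#' @return An object of class `panel_pipeline`: `fisher`, `rfe` (rankings),
#'   `pool` (with `overlap` attribute), `trials`, `frequency_table`, `panel`,
#'   `manifest` (config echo, derived seeds, stage content hashes).
#' @export
run_feature_selection_pipeline <- function(mat, labels,
                                           config = pipeline_config(),
                                           out_dir = NULL,
                                           progress = FALSE) {
  validate_expression_matrix(mat)
  say <- function(...) if (progress) message(...)
  say("S1: Fisher-score filter")
  fisher <- fisher_scores(class_stats(mat, labels))
  say("S2: SVM-RFE+CBR")
  rfe <- svm_rfe_cbr_rank(mat, labels, config)
  say("S3: pooling top lists")
  pool <- pool_top_n(fisher, rfe, config$n_filter_fisher,
                     config$n_filter_rfe)
  say("S4: ", config$n_sffs_trials, " randomized SFFS trials")
  trials <- run_randomized_trials(mat[, pool, drop = FALSE], labels, config,
                                  progress = progress)
  say("S5: frequency consolidation")
  cons <- consolidate_frequencies(trials, config$panel_size, fisher)
  manifest <- list(
    config = unclass(config),
    sffs_seeds = vapply(seq_len(config$n_sffs_trials),
                        function(t) derive_seed(config, "sffs", t),
                        integer(1)),
    stage_hashes = list(
      fisher = rlang::hash(fisher),
      rfe = rlang::hash(rfe),
      pool = rlang::hash(pool),
      trials = rlang::hash(lapply(trials, `[[`, "selected_subset")),
      panel = rlang::hash(cons$panel)
    )
  )
  out <- list(fisher = fisher, rfe = rfe, pool = pool, trials = trials,
              frequency_table = cons$frequency_table, panel = cons$panel,
              manifest = manifest)
  class(out) <- "panel_pipeline"
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_ranking_tsv <- function(ranking, path) {
  df <- data.frame(rank = seq_len(nrow(ranking)), ranking,
                   method = attr(ranking, "method"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_ranking_tsv(res$fisher, fp("ranking_fisher.tsv"))
  write_ranking_tsv(res$rfe, fp("ranking_svm_rfe_cbr.tsv"))
  utils::write.table(
    data.frame(gene_id = res$pool),
    fp("pool.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  subsets <- do.call(rbind, lapply(res$trials, function(tr)
    data.frame(trial = tr$trial_index, split_seed = tr$split_seed,
               gene_id = tr$selected_subset,
               objective = tr$objective_value)))
  utils::write.table(subsets, fp("trial_subsets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$frequency_table, fp("frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = res$panel), fp("panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.sffs_trial <- function(x, ...) {
  cat(sprintf("<sffs_trial> %d genes, objective %.4f (split_seed %d)\n",
              length(x$selected_subset), x$objective_value, x$split_seed))
  invisible(x)
}

#' @export
print.panel_pipeline <- function(x, ...) {
  cat("<panel_pipeline>\n")
  cat("  pool:", length(x$pool), "genes (overlap",
      attr(x$pool, "overlap"), ")\n")
  cat("  trials:", length(x$trials), "\n")
  cat("  panel:", paste(x$panel, collapse = " "), "\n")
  invisible(x)
}
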