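## Panel validation: re-clustering agreement, classifier-suite CV,
## decision-tree rule extraction, per-cluster drug-response summaries.

#' Re-cluster on a gene panel and score agreement with the original labels
#'
#' Runs multi-restart k-means++ on the panel-restricted matrix with k equal
#' to the number of original label values and reports the adjusted Rand index
#' against the original labels, together with the panel-restricted WCSS curve
#' (for checking that the elbow sharpens on the panel).
#'
#' @param mat Samples x genes matrix already restricted to the panel.
#' @param original_labels Labels the panel is meant to reproduce.
#' @param config A [pipeline_config()] (restarts, master seed).
#' @param k_max Upper end of the reported WCSS curve.
#' @return List with `solution` (a `cluster_solution`), `agreement`
#'   (adjusted Rand index), and `curve` (a `wcss_curve`).
#' @export
revalidate_clustering <- function(mat, original_labels,
                                  config = pipeline_config(),
                                  k_max = 10L) {
  validate_expression_matrix(mat)
  k <- length(unique(original_labels))
  seed <- derive_seed(config, "revalidate", 0L)
  sol <- kmeanspp_fit(mat, k, config$n_kmeans_restarts, seed = seed)
  agreement <- mclust::adjustedRandIndex(sol$labels, original_labels)
  curve <- wcss_curve(mat, 1L, min(k_max, nrow(mat) - 1L),
                      config$n_kmeans_restarts, seed = seed)
  list(solution = sol, agreement = agreement, curve = curve)
}

## ---- classifier suite --------------------------------------------------

# stratified fold assignment (1..n_folds per sample), deterministic in seed
make_folds <- function(labels, n_folds, seed) {
  withr::with_seed(seed, {
    folds <- integer(length(labels))
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    folds
  })
}

fit_and_predict <- function(classifier, xtr, ytr, xte, config, fit_seed) {
  switch(classifier,
    knn = {
      cc_levels <- levels(ytr)
      D <- sqdist_to_centers(xte, xtr)
      k <- 5L
      pred <- apply(D, 1L, function(d) {
        ord <- order(d, seq_along(d))
        votes <- table(factor(ytr[ord[seq_len(min(k, length(d)))]],
                              levels = cc_levels))
        cc_levels[which.max(votes)]
      })
      factor(pred, levels = cc_levels)
    },
    decision_tree = {
      df <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          parms = list(split = "gini"),
                          control = cart_control())
      predict(fit, data.frame(xte, check.names = FALSE), type = "class")
    },
    random_forest = {
      fit <- withr::with_seed(fit_seed,
        randomForest::randomForest(xtr, ytr, ntree = 200L))
      predict(fit, xte)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte)
    },
    logistic = {
      df <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- suppressWarnings(
        nnet::multinom(.y ~ ., df, trace = FALSE, maxit = 200L,
                       MaxNWts = 5000L))
      predict(fit, data.frame(xte, check.names = FALSE))
    },
    neural_net = {
      mu <- colMeans(xtr)
      s <- apply(xtr, 2L, stats::sd)
      s[s == 0 | is.na(s)] <- 1
      ztr <- sweep(sweep(xtr, 2L, mu, "-"), 2L, s, "/")
      zte <- sweep(sweep(xte, 2L, mu, "-"), 2L, s, "/")
      fit <- withr::with_seed(fit_seed,
        nnet::nnet(ztr, nnet::class.ind(ytr), size = 8L, decay = 0.01,
                   maxit = 300L, trace = FALSE, softmax = TRUE,
                   MaxNWts = 5000L))
      cl <- colnames(nnet::class.ind(ytr))
      factor(cl[max.col(predict(fit, zte), ties.method = "first")],
             levels = levels(ytr))
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

#' Cross-validate a classifier suite on the panel
#'
#' Stratified `n_cv_folds`-fold cross-validation repeated `n_cv_repeats`
#' times with seeds derived from the master seed (fold assignment is made
#' after a canonical sort of samples by id, so results are invariant to input
#' row order). Per-cluster accuracy is the recall of that cluster pooled over
#' the folds of a repeat, averaged over repeats; the macro average is the
#' mean of the per-cluster values. When the smallest class has fewer members
#' than `n_cv_folds` the fold count is reduced with a warning.
#'
#' The default suite spans six families: k-nearest neighbours (k = 5), a CART
#' decision tree, a random forest (200 trees), naive Bayes, multinomial
#' logistic regression, and a small feed-forward network (one hidden layer of
#' 8 units, weight decay 0.01, inputs z-scored per training fold).
#'
#' @param mat Samples x genes matrix restricted to the panel.
#' @param labels Cluster labels per sample.
#' @param config A [pipeline_config()].
#' @param classifiers Character vector selecting suite members.
#' @return An object of class `validation_report`: data frame with one row
#'   per classifier, per-cluster accuracy columns (percent), and an `average`
#'   column; protocol stored in the `protocol` attribute.
#' @export
crossvalidate_suite <- function(mat, labels, config = pipeline_config(),
                                classifiers = c("knn", "decision_tree",
                                                "random_forest",
                                                "naive_bayes", "logistic",
                                                "neural_net")) {
  validate_expression_matrix(mat)
  ord <- order(rownames(mat))           # canonical sample order
  mat <- mat[ord, , drop = FALSE]
  labels <- labels[ord]
  y <- factor(labels, levels = sort(unique(labels)))
  k_classes <- nlevels(y)
  n_folds <- config$n_cv_folds
  min_class <- min(table(y))
  if (min_class < n_folds) {
    n_folds <- min_class
    warning("reducing folds to smallest class size (", n_folds, ")",
            call. = FALSE)
  }
  if (n_folds < 2L) stop("degenerate class sizes: cannot cross-validate",
                         call. = FALSE)
  recall <- array(0, c(length(classifiers), k_classes, config$n_cv_repeats),
                  dimnames = list(classifiers, levels(y), NULL))
  for (r in seq_len(config$n_cv_repeats)) {
    folds <- make_folds(y, n_folds, derive_seed(config, "cv", r))
    correct <- matrix(0, length(classifiers), k_classes,
                      dimnames = list(classifiers, levels(y)))
    for (f in seq_len(n_folds)) {
      te <- folds == f
      for (cl in classifiers) {
        pred <- fit_and_predict(cl, mat[!te, , drop = FALSE], y[!te],
                                mat[te, , drop = FALSE], config,
                                fit_seed = derive_seed(config, paste0("cvfit_", cl, "_", r), f))
        hits <- pred == y[te]
        for (g in levels(y))
          correct[cl, g] <- correct[cl, g] + sum(hits & y[te] == g)
      }
    }
    class_sizes <- table(y)
    recall[, , r] <- sweep(correct, 2L, as.numeric(class_sizes), "/")
  }
  mean_recall <- apply(recall, c(1, 2), mean) * 100
  report <- data.frame(classifier = classifiers,
                       mean_recall,
                       average = rowMeans(mean_recall),
                       check.names = FALSE, row.names = NULL)
  attr(report, "protocol") <- list(n_folds = n_folds,
                                   n_repeats = config$n_cv_repeats,
                                   master_seed = config$master_seed)
  class(report) <- c("validation_report", "data.frame")
  report
}

## ---- decision tree and rule extraction ---------------------------------

cart_control <- function() {
  rpart::rpart.control(minsplit = 4L, minbucket = 2L, cp = 0,
                       maxcompete = 0L, maxsurrogate = 0L, xval = 0L)
}

#' Train a decision tree on the panel and extract its rules
#'
#' Fits a binary axis-aligned CART tree (Gini impurity, split thresholds at
#' midpoints between adjacent observed values, grown until leaves are pure or
#' hold fewer than 2 samples) and converts every root-to-leaf path into a
#' conjunction of `(gene, comparator, threshold)` predicates. Repeated
#' predicates on the same gene along a path are simplified (tightest bound
#' kept). The extracted rules are mutually exclusive and exhaustive over the
#' feature space and reproduce the tree's predictions exactly.
#'
#' @param mat Samples x genes matrix restricted to the panel.
#' @param labels Cluster labels per sample.
#' @param config A [pipeline_config()] (unused tuning hooks reserved).
#' @return List with `model` (the rpart fit) and `rules` (a `rule_set`).
#' @export
train_decision_tree <- function(mat, labels, config = pipeline_config()) {
  validate_expression_matrix(mat)
  y <- factor(labels, levels = sort(unique(labels)))
  df <- data.frame(.y = y, mat, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., df, method = "class",
                      parms = list(split = "gini"),
                      control = cart_control())
  list(model = fit, rules = extract_rules(fit))
}

#' Extract decision rules from a fitted rpart classification tree
#'
#' @param fit An rpart object grown with `maxcompete = 0, maxsurrogate = 0`.
#' @return An object of class `rule_set`: a list of rules, each with
#'   `predicates` (data frame `gene_id`, `comparator` (`"<"` or `">="`),
#'   `threshold`) and `cluster` (predicted label).
#' @export
extract_rules <- function(fit) {
  frame <- fit$frame
  ylevels <- attr(fit, "ylevels")
  node_ids <- as.integer(rownames(frame))
  is_leaf <- frame$var == "<leaf>"
  # with no competes/surrogates, non-leaf frame rows map 1:1, in order, onto
  # rows of fit$splits
  split_row <- integer(nrow(frame))
  split_row[!is_leaf] <- seq_len(sum(!is_leaf))

  path_rules <- list()
  walk <- function(node, preds) {
    i <- match(node, node_ids)
    if (is_leaf[i]) {
      path_rules[[length(path_rules) + 1L]] <<-
        list(predicates = simplify_predicates(preds),
             cluster = ylevels[frame$yval[i]])
      return(invisible())
    }
    sp <- fit$splits[split_row[i], , drop = FALSE]
    gene <- as.character(frame$var[i])
    thr <- unname(sp[1L, "index"])
    ncat <- unname(sp[1L, "ncat"])
    # ncat = -1: left child is x < threshold; ncat = +1: left is x >= threshold
    left_pred <- if (ncat < 0) list(gene, "<", thr) else list(gene, ">=", thr)
    right_pred <- if (ncat < 0) list(gene, ">=", thr) else list(gene, "<", thr)
    walk(2L * node, c(preds, list(left_pred)))
    walk(2L * node + 1L, c(preds, list(right_pred)))
  }
  if (all(is_leaf)) {
    # root-only tree: single unconditional rule
    path_rules[[1L]] <- list(
      predicates = data.frame(gene_id = character(0),
                              comparator = character(0),
                              threshold = numeric(0)),
      cluster = ylevels[frame$yval[1L]])
  } else {
    walk(1L, list())
  }
  structure(path_rules, class = "rule_set")
}

simplify_predicates <- function(preds) {
  if (!length(preds))
    return(data.frame(gene_id = character(0), comparator = character(0),
                      threshold = numeric(0)))
  df <- data.frame(
    gene_id = vapply(preds, `[[`, character(1), 1L),
    comparator = vapply(preds, `[[`, character(1), 2L),
    threshold = vapply(preds, function(p) as.numeric(p[[3L]]), numeric(1)),
    stringsAsFactors = FALSE)
  keep <- lapply(split(df, paste(df$gene_id, df$comparator)), function(g) {
    if (g$comparator[1L] == ">=") g[which.max(g$threshold), ]
    else g[which.min(g$threshold), ]
  })
  out <- do.call(rbind, keep)
  out[order(out$gene_id, out$comparator), , drop = FALSE]
}

#' Apply a rule set to new data
#'
#' @param rules A `rule_set` from [extract_rules()].
#' @param mat Samples x genes matrix containing the genes the rules use.
#' @return Character vector of predicted cluster labels; an error if some
#'   sample matches no rule (cannot happen for rules from a proper tree).
#' @export
predict_rules <- function(rules, mat) {
  pred <- rep(NA_character_, nrow(mat))
  n_hit <- integer(nrow(mat))
  for (rule in rules) {
    sat <- rep(TRUE, nrow(mat))
    prd <- rule$predicates
    for (q in seq_len(nrow(prd))) {
      v <- mat[, prd$gene_id[q]]
      sat <- sat & (if (prd$comparator[q] == "<") v < prd$threshold[q]
                    else v >= prd$threshold[q])
    }
    pred[sat] <- rule$cluster
    n_hit <- n_hit + as.integer(sat)
  }
  if (any(n_hit != 1L))
    stop("rule set is not exclusive/exhaustive on this input", call. = FALSE)
  pred
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set>", length(x), "rule(s)\n")
  for (rule in x) {
    prd <- rule$predicates
    lhs <- if (nrow(prd)) paste(sprintf("%s %s %.6g", prd$gene_id,
                                        prd$comparator, prd$threshold),
                                collapse = " & ")
           else "(always)"
    cat(sprintf("  %s -> cluster %s\n", lhs, rule$cluster))
  }
  invisible(x)
}

#' Rule set as a printable table
#'
#' @param rules A `rule_set`.
#' @return Data frame with columns `cluster` and `rule` (conjunction text).
#' @export
rules_table <- function(rules) {
  data.frame(
    cluster = vapply(rules, `[[`, character(1), "cluster"),
    rule = vapply(rules, function(rule) {
      prd <- rule$predicates
      if (!nrow(prd)) return("(always)")
      paste(sprintf("%s %s %.6g", prd$gene_id, prd$comparator,
                    prd$threshold), collapse = " & ")
    }, character(1)),
    stringsAsFactors = FALSE)
}

## ---- drug-response summaries -------------------------------------------

#' Per-cluster drug-response summary
#'
#' For every (cluster, drug) pair reports the number of samples with a
#' non-missing response, the mean, and the sample standard deviation
#' (ddof = 1, reported only when n >= 2). A per-drug monotonicity flag marks
#' drugs whose cluster means strictly decrease with cluster index.
#'
#' @param drugs Samples x drugs numeric matrix (ActArea; `NA` = missing).
#' @param labels Cluster labels named by sample id (samples in the drug table
#'   without a label are skipped with a message).
#' @param drug_subset Drug ids to summarize (default: all columns).
#' @return An object of class `drug_summary`: data frame with `cluster`,
#'   `drug`, `n`, `mean`, `sd`; per-drug decreasing-means flags in the
#'   `monotone_decreasing` attribute.
#' @export
drug_summary <- function(drugs, labels, drug_subset = colnames(drugs)) {
  if (length(drug_subset) < 1L) stop("empty drug subset", call. = FALSE)
  missing_drugs <- setdiff(drug_subset, colnames(drugs))
  if (length(missing_drugs))
    stop("unknown drug id(s): ", paste(missing_drugs, collapse = ", "),
         call. = FALSE)
  if (is.null(names(labels)))
    stop("labels must be named by sample id", call. = FALSE)
  known <- rownames(drugs) %in% names(labels)
  if (any(!known))
    message("skipping ", sum(!known), " unlabeled sample(s): ",
            paste(utils::head(rownames(drugs)[!known], 5L), collapse = ", "))
  drugs <- drugs[known, drug_subset, drop = FALSE]
  lab <- labels[rownames(drugs)]
  clusters <- sort(unique(labels))
  rows <- list()
  mono <- logical(length(drug_subset))
  names(mono) <- drug_subset
  for (d in drug_subset) {
    means <- numeric(0)
    for (cl in clusters) {
      v <- drugs[lab == cl, d]
      v <- v[!is.na(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, drug = d, n = n,
        mean = if (n >= 1L) mean(v) else NA_real_,
        sd = if (n >= 2L) stats::sd(v) else NA_real_)
      means <- c(means, if (n >= 1L) mean(v) else NA_real_)
    }
    mono[d] <- !anyNA(means) && all(diff(means) < 0)
  }
  out <- do.call(rbind, rows)
  attr(out, "monotone_decreasing") <- mono
  class(out) <- c("drug_summary", "data.frame")
  out
}
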