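## Fisher-score filter and SVM-RFE with correlation bias reduction.

#' Per-class summary statistics used by the Fisher score
#'
#' @param mat Samples x genes matrix.
#' @param labels Class labels, one per sample (any atomic type; classes are
#'   ordered by `sort(unique(labels))`).
#' @return An object of class `class_stats`: `class_means` and `class_sds`
#'   (genes x classes, sample-sd convention ddof = 1), `n_j` (class sizes),
#'   `overall_mean` (per gene), `classes`.
#' @export
class_stats <- function(mat, labels) {
  validate_expression_matrix(mat)
  if (length(labels) != nrow(mat))
    stop("labels must have one entry per sample", call. = FALSE)
  classes <- sort(unique(labels))
  n_j <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  singleton <- classes[n_j < 2L]
  if (length(singleton))
    stop("class with fewer than 2 members: ",
         paste(singleton, collapse = ", "), call. = FALSE)
  p <- ncol(mat)
  class_means <- matrix(NA_real_, p, length(classes),
                        dimnames = list(colnames(mat), as.character(classes)))
  class_sds <- class_means
  for (j in seq_along(classes)) {
    sub <- mat[labels == classes[j], , drop = FALSE]
    class_means[, j] <- colMeans(sub)
    class_sds[, j] <- apply(sub, 2L, stats::sd)
  }
  out <- list(class_means = class_means, class_sds = class_sds, n_j = n_j,
              overall_mean = colMeans(mat), classes = classes)
  class(out) <- "class_stats"
  out
}

#' Fisher scores and the induced feature ranking
#'
#' The Fisher score of gene i is the weighted between-class squared deviation
#' over the weighted within-class variance,
#' `S_i = sum_j n_j (mu_ij - mu_i)^2 / sum_j n_j sigma_ij^2`,
#' with `sigma_ij` the sample standard deviation (ddof = 1). A zero
#' denominator yields score 0 when the numerator is also 0 (gene constant
#' everywhere) and `+Inf` otherwise (perfect within-class constancy with
#' between-class separation, ranked first). Ties are broken by gene id.
#'
#' @param stats A [class_stats()] object.
#' @return An object of class `feature_ranking`: data frame with `gene_id`
#'   and `score` ordered best-first, `method` attribute `"fisher"`.
#' @export
fisher_scores <- function(stats) {
  stopifnot(inherits(stats, "class_stats"))
  n_j <- stats$n_j
  num <- as.vector((stats$class_means - stats$overall_mean)^2 %*% n_j)
  den <- as.vector(stats$class_sds^2 %*% n_j)
  s <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  gene_id <- rownames(stats$class_means)
  ord <- order(-s, gene_id)
  ranking <- data.frame(gene_id = gene_id[ord], score = s[ord],
                        stringsAsFactors = FALSE)
  attr(ranking, "method") <- "fisher"
  class(ranking) <- c("feature_ranking", "data.frame")
  ranking
}

# single-linkage groups of features whose |Pearson r| >= threshold
correlation_groups <- function(x, threshold) {
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  adj <- abs(r) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# per-feature squared-weight criterion summed over one-vs-one linear SVMs
svm_ovo_criterion <- function(x, labels, cost) {
  classes <- sort(unique(labels))
  crit <- numeric(ncol(x))
  for (a in seq_along(classes)[-length(classes)]) {
    for (b in (a + 1):length(classes)) {
      rows <- labels == classes[a] | labels == classes[b]
      y <- factor(labels[rows], levels = classes[c(a, b)])
      fit <- e1071::svm(x[rows, , drop = FALSE], y, kernel = "linear",
                        cost = cost, scale = FALSE)
      w <- crossprod(fit$coefs, fit$SV)
      crit <- crit + as.vector(w)^2
    }
  }
  crit
}

#' SVM-RFE ranking with correlation bias reduction
#'
#' Backward elimination ranking driven by a linear soft-margin SVM refit on
#' the surviving features at each round. Features are z-scored internally
#' (the input matrix is not mutated). Multiclass problems use one-vs-one
#' binary SVMs with the per-feature criterion summed over class pairs. While
#' more than `2 * n_filter_rfe` features remain, each round eliminates the
#' lowest-criterion `ceiling(rfe_elimination_fraction * remaining)` features;
#' after that, features are removed one at a time. Correlation bias
#' reduction: before an elimination batch is committed, the surviving
#' features are grouped by single linkage on `|Pearson r| >= threshold`; when
#' an entire group is scheduled for elimination in one batch, its
#' highest-criterion member is retained for the next round, so a correlated
#' group whose importance is split across members is never wiped out at once.
#'
#' @param mat Samples x genes matrix (>= 2 classes, each with >= 2 members).
#' @param labels Class labels per sample.
#' @param config A [pipeline_config()] supplying `n_filter_rfe`,
#'   `rfe_elimination_fraction` and the default correlation threshold.
#' @param cbr Apply the correlation-bias-reduction step (default `TRUE`).
#' @param correlation_threshold Override of the grouping threshold; values
#'   above 1 make group formation impossible, reproducing plain SVM-RFE.
#' @param cost SVM regularization constant C (default 1).
#' @return A `feature_ranking`: all input genes exactly once, best first;
#'   `score` is the reverse elimination index (higher = survived longer).
#' @export
svm_rfe_cbr_rank <- function(mat, labels, config = pipeline_config(),
                             cbr = TRUE,
                             correlation_threshold =
                               config$cbr_correlation_threshold,
                             cost = 1) {
  validate_expression_matrix(mat)
  if (length(labels) != nrow(mat))
    stop("labels must have one entry per sample", call. = FALSE)
  if (any(!is.finite(mat)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need >= 2 classes for SVM-RFE", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("every class needs >= 2 members", call. = FALSE)
  z <- zscore_columns(mat)
  remaining <- colnames(z)
  eliminated <- character(0)
  horizon <- 2L * config$n_filter_rfe
  while (length(remaining) > 0L) {
    if (length(remaining) == 1L) {
      eliminated <- c(eliminated, remaining)
      break
    }
    xs <- z[, remaining, drop = FALSE]
    crit <- svm_ovo_criterion(xs, labels, cost)
    names(crit) <- remaining
    m <- length(remaining)
    batch_size <- if (m > horizon)
      min(m, max(1L, ceiling(config$rfe_elimination_fraction * m)))
    else 1L
    ord <- order(crit, names(crit))          # worst first, ties by gene id
    batch <- names(crit)[ord[seq_len(batch_size)]]
    if (cbr && batch_size > 1L) {
      membership <- correlation_groups(xs, correlation_threshold)
      for (grp in split(names(membership), membership)) {
        if (length(grp) >= 2L && all(grp %in% batch)) {
          keep <- grp[order(-crit[grp], grp)][1L]
          batch <- setdiff(batch, keep)
        }
      }
    }
    eliminated <- c(eliminated, batch)
    remaining <- setdiff(remaining, batch)
  }
  ranking <- data.frame(gene_id = rev(eliminated),
                        score = as.numeric(seq_along(eliminated)),
                        stringsAsFactors = FALSE)
  attr(ranking, "method") <-
    if (cbr) "svm_rfe_cbr" else "svm_rfe"
  class(ranking) <- c("feature_ranking", "data.frame")
  ranking
}

#' Pool the top-n genes of two rankings, eliminating duplicates
#'
#' @param ranking_a,ranking_b `feature_ranking` objects.
#' @param n_a,n_b How many leading genes to take from each ranking.
#' @return Character vector of pooled gene ids (in first-seen order) with an
#'   `overlap` attribute giving the number of shared genes, so
#'   `length(pool) == n_a + n_b - overlap`.
#' @export
pool_top_n <- function(ranking_a, ranking_b, n_a, n_b) {
  if (n_a > nrow(ranking_a) || n_b > nrow(ranking_b))
    stop("requested top-n exceeds ranking length", call. = FALSE)
  top_a <- ranking_a$gene_id[seq_len(n_a)]
  top_b <- ranking_b$gene_id[seq_len(n_b)]
  pool <- union(top_a, top_b)
  attr(pool, "overlap") <- length(intersect(top_a, top_b))
  pool
}
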