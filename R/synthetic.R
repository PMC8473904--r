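#' Specification for a synthetic expression study
#'
#' Describes a samples x genes log2-scale expression matrix with `n_clusters`
#' well-separated sample clusters of unequal size, a small set of planted
#' cluster-informative genes, a few blocks of highly correlated features, and
#' a large majority of uninformative noise genes. Defaults emulate the scale
#' and structure of a bulk cell-line panel: 60 samples split roughly
#' 41/45/14% across three clusters, 2,000 genes of which 15 are informative,
#' three correlated 5-gene blocks, baselines uniform on [4, 14] (a log2-like
#' scale) and unit within-cluster standard deviation.
#'
#' @param n_samples,n_genes Matrix dimensions.
#' @param n_clusters Number of planted clusters (>= 2).
#' @param cluster_proportions Simplex weights, one per cluster.
#' @param n_informative Number of independently planted informative genes.
#' @param effect_size Cluster shift magnitude in units of
#'   `within_cluster_sd`.
#' @param n_correlated_blocks,block_size Count and size of correlated blocks.
#' @param block_correlation Within-cluster pairwise Pearson correlation of
#'   block members, in (0, 1).
#' @param baseline_mean_range Interval the per-gene baseline means are drawn
#'   from.
#' @param within_cluster_sd Within-cluster standard deviation (all genes).
#' @param seed Integer seed; identical specs give bit-identical matrices.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60L,
                           n_genes = 2000L,
                           n_clusters = 3L,
                           cluster_proportions = c(20, 22, 7) / 49,
                           n_informative = 15L,
                           effect_size = 3,
                           n_correlated_blocks = 3L,
                           block_size = 5L,
                           block_correlation = 0.9,
                           baseline_mean_range = c(4, 14),
                           within_cluster_sd = 1,
                           seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    cluster_proportions = as.numeric(cluster_proportions),
    n_informative = as.integer(n_informative),
    effect_size = as.numeric(effect_size),
    n_correlated_blocks = as.integer(n_correlated_blocks),
    block_size = as.integer(block_size),
    block_correlation = as.numeric(block_correlation),
    baseline_mean_range = as.numeric(baseline_mean_range),
    within_cluster_sd = as.numeric(within_cluster_sd),
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
    if (n_samples < 2L * n_clusters)
      stop("n_samples too small for n_clusters", call. = FALSE)
    if (length(cluster_proportions) != n_clusters)
      stop("cluster_proportions must have one weight per cluster",
           call. = FALSE)
    if (any(cluster_proportions <= 0) ||
        abs(sum(cluster_proportions) - 1) > 1e-9)
      stop("cluster_proportions must be positive and sum to 1",
           call. = FALSE)
    if (n_informative < 0 || n_correlated_blocks < 0 || block_size < 0)
      stop("counts must be non-negative", call. = FALSE)
    if (n_informative + n_correlated_blocks * block_size > n_genes)
      stop("n_informative + n_correlated_blocks * block_size exceeds n_genes",
           call. = FALSE)
    if (n_correlated_blocks > 0 &&
        (block_correlation <= 0 || block_correlation >= 1))
      stop("block_correlation must lie in (0, 1)", call. = FALSE)
    if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
    if (within_cluster_sd <= 0)
      stop("within_cluster_sd must be positive", call. = FALSE)
    if (length(baseline_mean_range) != 2L ||
        diff(baseline_mean_range) < 0)
      stop("baseline_mean_range must be an interval", call. = FALSE)
  })
  invisible(spec)
}

# largest-remainder apportionment of n_samples across clusters, each >= 1
cluster_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  counts <- pmax(counts, 1)
  while (sum(counts) > n) {
    i <- which.max(counts - raw)
    counts[i] <- counts[i] - 1
  }
  rem <- raw - counts
  while (sum(counts) < n) {
    i <- which.max(rem)
    counts[i] <- counts[i] + 1
    rem[i] <- -Inf
  }
  as.integer(counts)
}

# shift pattern for planted signal j over k clusters: each gene is
# high-expressing in one cluster and low-expressing in another (relative to
# the remaining clusters), with the (high, low) pair cycling across genes so
# every cluster receives both high- and low-expressing informative genes
shift_pattern <- function(j, k, effect) {
  s <- numeric(k)
  hi <- ((j - 1L) %% k) + 1L
  lo <- (j %% k) + 1L
  s[hi] <- effect
  s[lo] <- -effect
  s
}

#' Generate a synthetic expression matrix with planted structure
#'
#' Each gene g gets a baseline mean drawn uniformly from
#' `baseline_mean_range`. Noise genes are i.i.d. Normal around their baseline
#' with `within_cluster_sd`. Each informative gene is shifted by
#' `+effect_size * within_cluster_sd` in one cluster (its high-expressing
#' cluster) and by `-effect_size * within_cluster_sd` in another (its
#' low-expressing cluster); the (high, low) pair cycles across genes so every
#' cluster has both high- and low-expressing markers. Each correlated block
#' shares a latent cluster-informative
#' signal: member genes are `sqrt(rho) * latent + sqrt(1 - rho) * noise`, so
#' the within-cluster pairwise correlation equals `block_correlation` exactly
#' at the population level (and the effective cluster shift of a block member
#' is `sqrt(rho) * effect_size`).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (samples x genes) and `truth`, an object of
#'   class `synthetic_truth` holding `labels` (named integer vector),
#'   `informative_gene_ids`, `block_memberships` (named integer vector:
#'   gene id -> block), and `shifts` (per planted signal, per cluster, in sd
#'   units).
#' @export
generate_expression <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, {
    n <- spec$n_samples
    p <- spec$n_genes
    k <- spec$n_clusters
    sd0 <- spec$within_cluster_sd
    counts <- cluster_counts(n, spec$cluster_proportions)
    labels <- rep.int(seq_len(k), counts)
    wid_s <- nchar(as.character(n))
    wid_g <- nchar(as.character(p))
    sample_ids <- sprintf(paste0("S%0", wid_s, "d"), seq_len(n))
    gene_ids <- sprintf(paste0("G%0", wid_g, "d"), seq_len(p))
    names(labels) <- sample_ids

    n_block_genes <- spec$n_correlated_blocks * spec$block_size
    planted_pos <- sample.int(p, spec$n_informative + n_block_genes)
    info_pos <- planted_pos[seq_len(spec$n_informative)]
    block_pos <- planted_pos[-seq_len(spec$n_informative)]

    mu <- stats::runif(p, spec$baseline_mean_range[1L],
                       spec$baseline_mean_range[2L])
    mat <- matrix(stats::rnorm(n * p, sd = sd0), n, p,
                  dimnames = list(sample_ids, gene_ids))
    mat <- sweep(mat, 2L, mu, "+")

    shifts <- matrix(0, spec$n_informative + spec$n_correlated_blocks, k)
    for (j in seq_len(spec$n_informative)) {
      s <- shift_pattern(j, k, spec$effect_size)
      shifts[j, ] <- s
      mat[, info_pos[j]] <- mat[, info_pos[j]] + s[labels] * sd0
    }

    block_membership <- integer(0)
    if (spec$n_correlated_blocks > 0L) {
      rho <- spec$block_correlation
      for (b in seq_len(spec$n_correlated_blocks)) {
        s <- shift_pattern(spec$n_informative + b, k, spec$effect_size)
        shifts[spec$n_informative + b, ] <- s
        latent <- s[labels] * sd0 + stats::rnorm(n, sd = sd0)
        cols <- block_pos[(b - 1L) * spec$block_size + seq_len(spec$block_size)]
        for (g in cols) {
          mat[, g] <- mu[g] + sqrt(rho) * latent +
            sqrt(1 - rho) * stats::rnorm(n, sd = sd0)
        }
        bm <- rep.int(b, spec$block_size)
        names(bm) <- gene_ids[cols]
        block_membership <- c(block_membership, bm)
      }
    }

    truth <- structure(list(
      labels = labels,
      informative_gene_ids = gene_ids[info_pos],
      block_memberships = block_membership,
      shifts = shifts,
      cluster_sizes = counts,
      spec = spec
    ), class = "synthetic_truth")
    list(matrix = mat, truth = truth)
  })
}

#' Generate a per-cluster drug-response table
#'
#' Sample s in cluster c receives `Normal(cluster_means[c, d], response_sd)`
#' for each drug d, truncated at zero (ActArea is non-negative), after which
#' each cell is independently blanked with probability `missing_fraction`.
#'
#' @param truth A `synthetic_truth` (supplies sample ids and labels).
#' @param cluster_means Numeric matrix, clusters x drugs (column names become
#'   drug ids; unnamed columns get `DRUG1`, ...).
#' @param response_sd Positive standard deviation of the response noise.
#' @param missing_fraction Probability a cell is missing, in [0, 1).
#' @param seed Integer seed.
#' @return Samples x drugs numeric matrix with `NA` for missing entries.
#' @export
generate_drug_response <- function(truth, cluster_means, response_sd,
                                   missing_fraction = 0, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cluster_means <- as.matrix(cluster_means)
  k <- length(unique(truth$labels))
  if (nrow(cluster_means) != k)
    stop("cluster_means must have one row per cluster", call. = FALSE)
  if (response_sd < 0) stop("response_sd must be non-negative", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must lie in [0, 1)", call. = FALSE)
  if (is.null(colnames(cluster_means)))
    colnames(cluster_means) <- paste0("DRUG", seq_len(ncol(cluster_means)))
  withr::with_seed(seed, {
    n <- length(truth$labels)
    d <- ncol(cluster_means)
    vals <- cluster_means[truth$labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = response_sd), n, d)
    vals <- pmax(vals, 0)
    dimnames(vals) <- list(names(truth$labels), colnames(cluster_means))
    if (missing_fraction > 0) {
      blank <- matrix(stats::runif(n * d) < missing_fraction, n, d)
      vals[blank] <- NA_real_
    }
    vals
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat("  samples:", length(x$labels),
      " clusters:", paste(x$cluster_sizes, collapse = "/"), "\n")
  cat("  informative genes:", length(x$informative_gene_ids), "\n")
  cat("  correlated block genes:", length(x$block_memberships), "\n")
  invisible(x)
}
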