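## Multi-restart k-means++ clustering, WCSS curves, elbow detection, PCA.

# squared Euclidean distances between rows of x and rows of centers
sqdist_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  pmax(d2, 0)
}

# greedy k-means++ D^2-weighted initialization (the standard variant: at
# each step several D^2-sampled candidates are drawn and the one that most
# reduces the potential is kept); returns row indices of x
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k == 1L) return(idx)
  n_cand <- 2L + as.integer(floor(log(k)))
  d2 <- sqdist_to_centers(x, x[idx[1L], , drop = FALSE])[, 1L]
  for (j in 2:k) {
    tot <- sum(d2)
    if (tot <= 0) {
      # all remaining points coincide with chosen centers: pick any new index
      candidates <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- candidates[sample.int(length(candidates), 1L)]
      d2 <- pmin(d2, sqdist_to_centers(x, x[idx[j], , drop = FALSE])[, 1L])
      next
    }
    cand <- sample.int(n, n_cand, replace = TRUE, prob = d2 / tot)
    pots <- vapply(cand, function(ci) {
      sum(pmin(d2, sqdist_to_centers(x, x[ci, , drop = FALSE])[, 1L]))
    }, numeric(1))
    idx[j] <- cand[which.min(pots)]
    d2 <- pmin(d2, sqdist_to_centers(x, x[idx[j], , drop = FALSE])[, 1L])
  }
  idx
}

# Lloyd iterations with farthest-point repair of empty clusters
lloyd <- function(x, centers, max_iter = 300L) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to_centers(x, centers)
    assign_cur <- max.col(-d2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(assign_cur))
    for (e in empty) {
      # re-seed the empty center at the point farthest from its own center
      dist_own <- d2[cbind(seq_len(n), assign_cur)]
      # only steal from clusters that keep >= 1 member
      sizes <- tabulate(assign_cur, nbins = k)
      eligible <- sizes[assign_cur] > 1L
      dist_own[!eligible] <- -Inf
      far <- which.max(dist_own)
      centers[e, ] <- x[far, ]
      assign_cur[far] <- e
      d2[, e] <- sqdist_to_centers(x, centers[e, , drop = FALSE])[, 1L]
    }
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (j in seq_len(k)) {
      members <- assign_cur == j
      if (any(members)) centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  d2 <- sqdist_to_centers(x, centers)
  assign_cur <- max.col(-d2, ties.method = "first")
  list(labels = assign_cur, centers = centers,
       point_d2 = d2[cbind(seq_len(n), assign_cur)])
}

#' Multi-restart k-means++ clustering
#'
#' Centers are initialized by the k-means++ D^2-sampling rule, refined by
#' Lloyd iterations to an assignment fixed point (300-iteration cap), with
#' empty clusters repaired by re-seeding at the point farthest from its own
#' center. Among `n_restarts` independently seeded restarts the
#' minimum-WCSS solution is returned. Restart r uses
#' `derive_seed(seed, "kmeans_restart", r)`, so restart seed sets are nested:
#' increasing `n_restarts` can only improve (never worsen) the returned WCSS.
#'
#' @param mat Samples x genes numeric matrix.
#' @param k Number of clusters, `1 <= k <= nrow(mat)`.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed (or a `pipeline_config`).
#' @param standardize Z-score genes before clustering (default `FALSE`:
#'   expression values already share a common scale).
#' @param squared Use squared Euclidean distances in the reported WCSS
#'   (default `TRUE`, the k-means objective); `FALSE` reports the unsquared
#'   sum of distances.
#' @return An object of class `cluster_solution`: `k`, `labels` (named,
#'   1..k), `centers`, `wcss`, `restart_seed`.
#' @export
kmeanspp_fit <- function(mat, k, n_restarts = 10L, seed = 1L,
                         standardize = FALSE, squared = TRUE) {
  validate_expression_matrix(mat)
  n <- nrow(mat)
  if (k < 1L || k > n)
    stop("k must lie in [1, number of samples]", call. = FALSE)
  x <- if (standardize) zscore_columns(mat) else mat
  master <- if (inherits(seed, "pipeline_config")) seed$master_seed else seed
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rs <- derive_seed(master, "kmeans_restart", r)
    fit <- withr::with_seed(rs, {
      init <- kmeanspp_init(x, k)
      lloyd(x, x[init, , drop = FALSE])
    })
    wcss <- if (squared) sum(fit$point_d2) else sum(sqrt(fit$point_d2))
    if (is.null(best) || wcss < best$wcss) {
      best <- list(k = k, labels = stats::setNames(fit$labels, rownames(mat)),
                   centers = fit$centers, wcss = wcss, restart_seed = rs)
    }
  }
  class(best) <- "cluster_solution"
  best
}

#' WCSS curve over a range of k
#'
#' One [kmeanspp_fit()] per k (each the best of `n_restarts` restarts, seeded
#' independently via [derive_seed()]); used for elbow analysis.
#'
#' @inheritParams kmeanspp_fit
#' @param k_min,k_max Scanned range, `1 <= k_min < k_max <= n`.
#' @return An object of class `wcss_curve`: data frame with columns `k`,
#'   `wcss`, `best_restart_seed`.
#' @export
wcss_curve <- function(mat, k_min = 1L, k_max = 10L, n_restarts = 10L,
                       seed = 1L, standardize = FALSE, squared = TRUE) {
  if (k_min < 1L || k_min >= k_max || k_max > nrow(mat))
    stop("require 1 <= k_min < k_max <= number of samples", call. = FALSE)
  master <- if (inherits(seed, "pipeline_config")) seed$master_seed else seed
  ks <- k_min:k_max
  rows <- lapply(ks, function(k) {
    fit <- kmeanspp_fit(mat, k, n_restarts,
                        seed = derive_seed(master, "wcss_k", k),
                        standardize = standardize, squared = squared)
    data.frame(k = k, wcss = fit$wcss, best_restart_seed = fit$restart_seed)
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("wcss_curve", "data.frame")
  curve
}

#' Detect the elbow of a WCSS curve
#'
#' Normalizes the curve to the unit square and scores each interior k by the
#' discrete curvature (second difference) of the normalized WCSS. The elbow
#' is the interior k with maximal curvature; when the maximum falls below
#' `strength_threshold` the curve is judged "near-straight" and no elbow is
#' reported. An exactly linear curve has zero second differences everywhere,
#' so it can never trigger detection.
#'
#' @param curve A `wcss_curve` (or data frame with `k` and `wcss`), >= 4
#'   entries with strictly increasing k.
#' @param strength_threshold Minimal normalized curvature accepted as an
#'   elbow (default 0.1).
#' @return An object of class `elbow_report`: `k_elbow` (or `NA`),
#'   `curvature_scores` (named by interior k), `detected`.
#' @export
detect_elbow <- function(curve, strength_threshold = 0.1) {
  if (nrow(curve) < 4L) stop("curve must have >= 4 entries", call. = FALSE)
  if (any(diff(curve$k) <= 0))
    stop("k values must be strictly increasing", call. = FALSE)
  w <- curve$wcss
  rng <- max(w) - min(w)
  y <- if (rng > 0) (w - min(w)) / rng else rep(0, length(w))
  i <- 2:(length(y) - 1L)
  curv <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  names(curv) <- curve$k[i]
  best <- which.max(curv)
  detected <- curv[best] >= strength_threshold
  rep <- list(
    k_elbow = if (detected) curve$k[i][best] else NA_integer_,
    curvature_scores = curv,
    detected = detected
  )
  class(rep) <- "elbow_report"
  rep
}

#' 2-D (or higher) PCA projection for cluster visualization
#'
#' Column-centered (not scaled) projection onto the leading principal axes.
#' The sign of each axis is fixed so that its largest-magnitude loading is
#' positive, making projections reproducible across platforms.
#'
#' @param mat Samples x genes matrix.
#' @param n_components Number of components (default 2).
#' @return List with `scores` (samples x components), `explained_variance`
#'   (fraction of total variance per component, non-increasing) and
#'   `loadings`.
#' @export
pca_project <- function(mat, n_components = 2L) {
  validate_expression_matrix(mat)
  if (n_components > min(dim(mat)))
    stop("n_components exceeds min(samples, genes)", call. = FALSE)
  total_var <- sum(apply(mat, 2L, stats::var))
  if (total_var <= 0)
    stop("degenerate matrix: all genes constant", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x,
       explained_variance = pc$sdev[seq_len(n_components)]^2 /
         sum(pc$sdev^2),
       loadings = pc$rotation)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, wcss = %.6g, sizes = %s\n",
              x$k, x$wcss,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' @export
print.elbow_report <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<elbow_report> elbow at k = %d (curvature %.3f)\n",
                x$k_elbow, max(x$curvature_scores)))
  } else {
    cat(sprintf(
      "<elbow_report> no elbow detected (max curvature %.3f)\n",
      max(x$curvature_scores)))
  }
  invisible(x)
}

zscore_columns <- function(mat) {
  mu <- colMeans(mat)
  s <- apply(mat, 2L, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  sweep(sweep(mat, 2L, mu, "-"), 2L, s, "/")
}
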