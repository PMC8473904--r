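---
title: "Clustering expression profiles and distilling discriminative gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering expression profiles and distilling discriminative gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a continuous expression matrix over a modest number of samples (tens of
cell lines or specimens) and a very large number of genes, two questions are
asked in sequence:

1. Do the samples fall into a small number of well-separated genomic
   clusters?
2. Which compact set of genes suffices to tell those clusters apart, across
   many different kinds of classifiers?

At this sample-to-feature ratio single feature-selection algorithms are
unstable: different algorithms, or the same algorithm on different random
splits, return largely disjoint gene lists, and almost any sufficiently large
random gene set classifies well. `clusterpanel` therefore consolidates three
very different selectors and many randomized trials into one pipeline, and
accepts a gene only when it keeps being chosen.

## The procedure

**Clustering.** Samples are clustered by k-means++ — Lloyd iterations from
D^2-weighted random initializations — minimizing the within-cluster sum of
squares (WCSS). Every fit is the best of `n_kmeans_restarts` (default 10)
independently seeded restarts. The number of clusters is read off the
WCSS-versus-k curve at its elbow. `detect_elbow()` automates the usual visual
judgement: the curve is min-max normalized and each interior k is scored by
the discrete second difference; the maximum, if it exceeds
`strength_threshold` (default 0.1), is the elbow. An exactly straight line
has zero second difference everywhere and can never trigger detection, which
is the desired behaviour for feature sets that do not structure the samples.
Two-dimensional PCA projections (`pca_project()`, column-centred, sign-fixed
so the largest-magnitude loading is positive) support visual inspection, and
`exclude_samples()` removes curated-out samples before re-clustering.

**Feature selection.** With cluster indices as the response, the pipeline
(`run_feature_selection_pipeline()`) runs five stages:

* S1 — Fisher-score filter. For gene i with per-class means
  $\mu_{ij}$, per-class sample standard deviations $\sigma_{ij}$ and class
  sizes $n_j$,
  $S_i = \sum_j n_j(\mu_{ij}-\mu_i)^2 \big/ \sum_j n_j \sigma_{ij}^2$.
  The top `n_filter_fisher` (default 500) genes are kept.
* S2 — SVM-RFE with correlation bias reduction. A linear soft-margin SVM
  (C = 1, features z-scored internally, multiclass one-vs-one with the
  per-feature criterion summed over class pairs) is refit while the
  lowest-weight features are recursively eliminated — 10% of the survivors
  per round far from the reporting horizon, one at a time once at most
  `2 * n_filter_rfe` remain. Before a batch is committed, features are
  grouped by single linkage on |Pearson r| >= `cbr_correlation_threshold`
  (default 0.85); a group about to be eliminated wholesale keeps its
  best member for the next round, so a correlated group whose importance the
  SVM splits across members is never wiped out at once. The top
  `n_filter_rfe` (default 500) genes are kept.
* S3 — the two lists are pooled with deduplication (`pool_top_n()`).
* S4 — `n_sffs_trials` (default 500) randomized trials of sequential
  floating forward search (SFFS) wrapped around a KNN objective: each trial
  draws its own stratified 70/30 train/test split and greedily grows a
  subset to `sffs_subset_size` (default 20) genes, with conditional backward
  steps accepted while they strictly improve on the best recorded smaller
  subset. The objective is the mean test accuracy of Euclidean KNN over
  k in `knn_k_values` (default 3–9).
* S5 — genes are ranked by how many trial subsets contain them, and the top
  `panel_size` (default 15) form the panel. The full frequency table is kept
  for inspection; its hallmark on clusterable data is a steep drop in
  occurrence counts just past the genuinely informative genes.

**Validation.** `revalidate_clustering()` re-runs k-means++ on the
panel-restricted matrix and reports the adjusted Rand index against the
original labels, plus the panel-restricted WCSS curve (the elbow typically
sharpens dramatically on a good panel). `crossvalidate_suite()` estimates
per-cluster recall for six classifier families (KNN, CART decision tree,
random forest, naive Bayes, multinomial logistic regression, a small
feed-forward network) under stratified 10-fold cross-validation repeated 10
times. `train_decision_tree()` grows a CART tree (Gini, midpoint thresholds,
pure leaves or minimum leaf size 2) and `extract_rules()` converts it to a
table of (gene, comparator, threshold) conjunctions that reproduce the tree's
predictions exactly. `drug_summary()` reports per-(cluster, drug) sample
size, mean and sample standard deviation of ActArea drug responses, with a
flag for drugs whose cluster means decrease monotonically across clusters.

## Reproducibility model

Every source of randomness is derived from one `master_seed` through a
hash-based `derive_seed(master, stage_label, trial_index)`. Trials are
therefore independently seeded yet bit-reproducible, order-independent and
embarrassingly parallel in principle; two runs with the same master seed
produce byte-identical rankings, frequency tables and panels.

## Numerical and design choices

* **WCSS is the sum of squared Euclidean distances** to the assigned
  centers — the quantity k-means actually minimizes. An unsquared variant is
  available (`squared = FALSE`) for comparison with descriptions that speak
  loosely of "sum of distances".
* **Greedy k-means++ initialization.** Each new center is chosen among
  `2 + floor(log k)` D^2-sampled candidates as the one minimizing the
  potential — the variant evaluated alongside the original algorithm and the
  default in mainstream implementations. It measurably raises the rate at
  which 10 restarts reach the global optimum on small instances.
* **Empty-cluster repair.** If a Lloyd update empties a cluster, its center
  is re-seeded at the point farthest from its own center (stealing only from
  clusters that keep at least one member).
* **No feature standardization by default.** Log-scale expression values
  share a common scale; z-scoring is available (`standardize = TRUE`) and is
  always applied internally to the SVM in RFE, which is scale-sensitive.
* **Deterministic KNN.** Neighbour-distance ties are broken by training
  sample order and vote ties by the lowest class index, making the wrapper
  objective a pure function of (subset, split). KNN k values at or above the
  smallest training class are allowed with a warning: neighbourhoods then
  necessarily span classes, which mirrors real panels whose smallest cluster
  is tiny.
* **SFFS tie handling.** The KNN objective has resolution of roughly one
  part in (test samples x k values), so on well-separated data it plateaus
  and many candidate genes tie. Ties are resolved toward the candidate with
  the higher Fisher score computed on a stratified bootstrap of the trial's
  training samples, with a per-trial random order as the final tie-break.
  Rationale: a tie order shared across trials (e.g. lexicographic) would add
  the same arbitrary genes to every trial's subset and let them dominate the
  frequency ranking, defeating the purpose of randomized trials;
  a purely random order scatters plateau picks over the whole pool and
  drowns the counts of genuinely informative genes. The bootstrap-Fisher
  rule keeps plateau picks concentrated on marginally relevant genes while
  staying independent across trials and using no test-split information.
* **Backward-step acceptance** requires strictly exceeding the best recorded
  value at the smaller size, which guarantees termination.
* **Fisher-score conventions.** Sample standard deviations (ddof = 1). A
  zero denominator yields score 0 when the numerator is 0 and +Inf
  otherwise; +Inf ranks first. Remaining ties break by gene id.
* **Decision tree.** CART with Gini impurity; split thresholds are midpoints
  between adjacent observed values; growth to pure leaves with minimum leaf
  size 2, because the tree is grown on a small panel for rule *extraction*
  rather than prediction. The suite's tree classifier uses the same
  controls.
* **Cross-validation accuracy** is per-cluster recall pooled over folds and
  averaged over repeats; the macro average is the unweighted mean across
  clusters — the only reading under which a per-cluster table and an
  "average" row are mutually consistent. Folds are assigned after a
  canonical sort of samples by id, so results do not depend on input row
  order.
* **ActArea is non-negative**, so the drug-response generator truncates
  Normal draws at zero; at realistic signal-to-noise this bias is far below
  sampling noise.

## The synthetic-data generator

`generate_expression()` emulates the statistical structure the analysis
assumes, so that every stage is testable with known ground truth:

* Gene baselines are uniform on `[4, 14]` — the range of log2-like
  expression values where real decision thresholds live — with Gaussian
  within-cluster noise of equal variance (sd 1 by default) in every cluster.
* Cluster sizes are deliberately unequal (default proportions roughly
  41/45/14%, echoing a published three-cluster panel of 20/22/7 cell
  lines).
* Each informative gene is high-expressing in one cluster and
  low-expressing in another (+/- `effect_size` in within-cluster sd units),
  with the (high, low) pair cycling so every cluster owns both high and low
  markers — the structure seen in real panel heatmaps.
* Correlated blocks share a latent, cluster-informative factor; member genes
  are `sqrt(rho) * latent + sqrt(1-rho) * noise`, so the *within-cluster*
  pairwise correlation is exactly `block_correlation` at the population
  level. (The marginal correlation across clusters is higher, because block
  members also share their cluster shifts; the conditional parameter is the
  one the construction can pin exactly.)
* `generate_drug_response()` draws per-sample ActArea values around
  specified per-(cluster, drug) means, truncated at zero, with independent
  Bernoulli missingness.

What the generator does **not** emulate: the broad gene-gene correlation
structure of real transcriptomes (outside the planted blocks, noise genes
are independent), probe-level artifacts, batch effects, heavy-tailed or
count-distributed noise, and any coupling between drug response and
individual gene values beyond cluster membership. Passing tests on this
generator therefore demonstrate that the pipeline recovers structure *of the
planted kind*; they cannot certify behaviour under correlated noise that
mimics informative signal.

## Problem sizes used by the test suite

The tests run the full design at desk scale, chosen so the suite completes
in a few minutes while keeping every stage's behaviour visible: the
end-to-end study uses 60 samples x 2,000 genes with 15 planted informative
genes at effect size 3, filters at 100 + 100, 50 SFFS trials of 10-gene
subsets and a 15-gene panel; elbow analyses use 60 x 200 (a sparse planted
truth contributes a fixed amount of between-cluster variance, so at very
large gene counts the elbow of a 15-gene signal is invisible by
construction — real data sets earn their elbows from thousands of co-varying
genes, which the generator deliberately does not emulate); the SFFS-versus-
exhaustive comparison uses 10-gene pools where C(10,3) subsets can be
enumerated; and correlation-bias-reduction checks use one informative gene
duplicated five times among 200 noise genes, where aggressive batch
elimination demonstrably discards the whole duplicated group unless the CBR
step rescues a representative.

## Known limitations

* The wrapper stage is O(pool x subset size) objective evaluations per
  trial; it is meant for pooled candidate sets (hundreds of genes), not the
  raw 19k-gene matrix — which is exactly why the filter stages exist.
* With subsets smaller than the panel, the panel's tail ranks depend on
  cross-trial diversity; a panel larger than the subset size is only
  meaningful when trials disagree somewhat (see the tie-handling note
  above).
* Per-cluster recall from 10-fold CV on tiny clusters (a handful of
  samples) is coarse; fold counts are reduced automatically, with a warning,
  when a class is smaller than the fold count.
* `detect_elbow()` scores curvature after min-max normalization; WCSS curves
  that decay smoothly (near-exponentially) without a knee will produce a
  weak maximum somewhere — the strength threshold, not the argmax alone,
  decides whether to report an elbow.
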