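#' Z-score normalize pooled stable-state expressions
#'
#' Column-wise z-scoring of the pooled stable steady states of all models
#' (log2 levels).  The per-gene centers and scales are returned so that
#' perturbed (e.g. knockout) data can be normalized with the unperturbed
#' ensemble's parameters.
#'
#' @param states Matrix (or data frame) of log2 expression levels, one row
#'   per stable state, one column per gene (see [expression_matrix()]).
#' @param center,scale Optional per-gene means and standard deviations to
#'   apply instead of computing them from `states` (use the unperturbed
#'   ensemble's values when normalizing perturbed data).
#' @return The z-scored matrix, with attributes `center` and `scale`.
#' @export
normalize_expressions <- function(states, center = NULL, scale = NULL) {
  m <- as.matrix(states)
  if (nrow(m) < 2L) stop("need at least 2 states to normalize")
  if (is.null(center)) center <- colMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 2, stats::sd)
    zero <- which(scale == 0)
    if (length(zero)) {
      stop("zero-variance gene(s): ",
           paste(colnames(m)[zero], collapse = ", "),
           " (normalize with reference center/scale instead)")
    }
  }
  z <- sweep(sweep(m, 2, center, `-`), 2, scale, `/`)
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

#' Hierarchical clustering of ensemble expression states
#'
#' Average-linkage agglomerative clustering on Euclidean distances of the
#' normalized states.  "Major" clusters — those holding at least `cutoff`
#' of all states — are the robust gene states of the circuit.  The cut is
#' selected by persistence: cut sizes `k = 1..max_k` are scanned (by
#' default up to `1/cutoff`, the largest number of major clusters the
#' cutoff permits), and the major-cluster count that stays constant over
#' the longest consecutive stretch of `k` is accepted, ties toward the
#' earliest stretch; the tree is cut at that stretch's smallest `k`
#' (fewest clusters).  A persistent count means the extra cuts are being
#' absorbed by sub-`cutoff` fragments — the signature of real separated
#' patterns — whereas maximizing the raw count over all cut heights is
#' degenerate (splitting one tight cluster into balanced halves keeps
#' producing above-cutoff pieces).
#'
#' @param z Normalized expression matrix from [normalize_expressions()].
#' @param cutoff Minimum fraction of states for a cluster to count as
#'   major (default 5%).
#' @param max_k Largest cut size examined; default `floor(1/cutoff)`.
#' @return An object of class `racipe_clusters`: list with `labels`
#'   (integer cluster id per state), `sizes` (tibble: cluster, n,
#'   fraction, major), `n_major`, `k`, `cutoff`, `tree` (the hclust).
#' @export
hierarchical_clusters <- function(z, cutoff = 0.05, max_k = NULL) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 states to cluster")
  if (is.null(max_k)) max_k <- max(2L, floor(1 / cutoff))
  tree <- stats::hclust(stats::dist(z), method = "average")
  n <- nrow(z)
  ks <- seq_len(min(max_k, n))
  counts <- vapply(ks, function(k) {
    sum(tabulate(stats::cutree(tree, k = k), nbins = k) / n >= cutoff)
  }, numeric(1))
  runs <- rle(counts)
  sel <- which.max(runs$lengths)  # longest persistent count, earliest tie
  best_k <- ks[sum(runs$lengths[seq_len(sel - 1)]) + 1L]
  labels <- stats::cutree(tree, k = best_k)
  sizes <- tibble::tibble(
    cluster = seq_len(best_k),
    n = tabulate(labels, nbins = best_k)
  )
  sizes$fraction <- sizes$n / nrow(z)
  sizes$major <- sizes$fraction >= cutoff
  structure(list(labels = labels, sizes = sizes,
                 n_major = sum(sizes$major), k = best_k,
                 cutoff = cutoff, tree = tree),
            class = "racipe_clusters")
}

#' @export
print.racipe_clusters <- function(x, ...) {
  cat("<racipe_clusters> ", length(x$labels), " states, cut at k = ", x$k,
      "; ", x$n_major, " major clusters (>= ",
      format(100 * x$cutoff), "% of states)\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' @export
tidy.racipe_clusters <- function(x, ...) {
  x$sizes
}

#' @export
glance.racipe_clusters <- function(x, ...) {
  tibble::tibble(n_states = length(x$labels), k = x$k,
                 n_major = x$n_major, cutoff = x$cutoff)
}

#' Principal components of the normalized expression states
#'
#' Standard PCA of the pooled z-scored states.  Components are sign-fixed
#' so that each component's largest-magnitude loading is positive
#' (determinism).  Perturbed data are projected onto the unperturbed
#' components with [project_states()]; for a knockout the knocked-out
#' gene's column must first be set to its zero-expression z-coordinate
#' under the unperturbed normalization, so the component axes reflect the
#' zero expression.
#'
#' @param z Normalized expression matrix.
#' @return An object of class `racipe_pca`: list with `rotation` (gene x
#'   component loadings), `sdev`, and `scores` (tibble `PC1`, `PC2`, ...).
#' @export
racipe_pca <- function(z) {
  z <- as.matrix(z)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(p$rotation, 2, flip, `*`)
  scores <- z %*% rotation
  structure(list(rotation = rotation, sdev = p$sdev,
                 scores = tibble::as_tibble(as.data.frame(scores))),
            class = "racipe_pca")
}

#' @rdname racipe_pca
#' @param pca A `racipe_pca` fitted on reference (unperturbed) states.
#' @param z_new Matrix normalized with the reference center/scale.
#' @return `project_states()`: tibble of component scores for `z_new`.
#' @export
project_states <- function(pca, z_new) {
  stopifnot(inherits(pca, "racipe_pca"))
  s <- as.matrix(z_new) %*% pca$rotation
  tibble::as_tibble(as.data.frame(s))
}

#' @export
tidy.racipe_pca <- function(x, ...) {
  x$scores
}

#' Distribution of the number of stable states per model
#'
#' @param x A `racipe_ensemble`, or an integer vector of per-model state
#'   counts.
#' @param max_count Optional fixed support upper end `0..max_count`
#'   (use a common value to compare ensembles).
#' @return A tibble with columns `n_states` (0, 1, 2, ...) and `prob`,
#'   summing to 1 over models.
#' @export
state_count_distribution <- function(x, max_count = NULL) {
  counts <- if (inherits(x, "racipe_ensemble")) x$params$n_states else
    as.integer(x)
  stopifnot(length(counts) >= 1, all(counts >= 0))
  if (is.null(max_count)) max_count <- max(counts)
  stopifnot(max_count >= max(counts))
  tibble::tibble(
    n_states = 0:max_count,
    prob = tabulate(counts + 1L, nbins = max_count + 1L) / length(counts)
  )
}

# coerce a distribution argument (prob vector or state-count tibble) to a
# bare probability vector; tibbles must share support to be comparable
dist_vec <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(all(c("n_states", "prob") %in% names(p)))
    return(p$prob)
  }
  as.numeric(p)
}

#' Bhattacharyya distance between two distributions
#'
#' \eqn{D_B = -\ln \sum_x \sqrt{p(x) q(x)}}: 0 iff the distributions are
#' identical, growing as they diverge.  It is symmetric but does not obey
#' the triangle inequality.  Zero-overlap distributions have infinite
#' distance, reported as the cap (700, about \eqn{-\ln} of the smallest
#' positive double).
#'
#' @param p,q Probability vectors on a shared support (or state-count
#'   tibbles from [state_count_distribution()] built with a common
#'   `max_count`).
#' @param cap Value reported for infinite (zero-overlap) distance.
#' @return Non-negative scalar dissimilarity.
#' @examples
#' bhattacharyya(c(1, 0), c(0.5, 0.5))  # -log(sqrt(0.5))
#' @export
bhattacharyya <- function(p, q, cap = 700) {
  p <- dist_vec(p); q <- dist_vec(q)
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("distributions must be normalized (sum to 1)")
  }
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  bc <- sum(sqrt(p * q))
  if (bc <= 0) return(cap)
  min(-log(bc), cap)
}

#' @rdname bhattacharyya
#' @details `kl_divergence()` is the alternative (asymmetric) metric
#'   \eqn{D_{KL}(p \| q) = \sum_x p(x) \ln(p(x)/q(x))}; also 0 iff the
#'   distributions are equal.
#' @export
kl_divergence <- function(p, q, cap = 700) {
  p <- dist_vec(p); q <- dist_vec(q)
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("distributions must be normalized (sum to 1)")
  }
  i <- p > 0
  if (any(q[i] == 0)) return(cap)
  min(sum(p[i] * log(p[i] / q[i])), cap)
}

#' Average replicate dissimilarity between two simulation settings
#'
#' The convergence diagnostic: given independent replicate distributions
#' at a test setting and at the reference (largest) setting, the
#' dissimilarity is the average pairwise distance over all replicate
#' pairs,
#' \deqn{D = \frac{1}{J H} \sum_{j=1}^{J} \sum_{h=1}^{H} D_B(p_j, q_h),}
#' (10 replicates each by convention, giving the 1/100 average).  Applied
#' to state-count distributions it is the "dissimilarity of states"; to
#' binned per-gene expression histograms, the "dissimilarity of
#' expressions".
#'
#' @param reps,refs Lists of distributions (probability vectors on a
#'   shared support, or state-count tibbles with a common `max_count`).
#' @param metric `"bhattacharyya"` (default) or `"kl"`.
#' @param cap Cap for infinite distances.
#' @return Mean pairwise dissimilarity (non-negative scalar).
#' @export
replicate_dissimilarity <- function(reps, refs,
                                    metric = c("bhattacharyya", "kl"),
                                    cap = 700) {
  metric <- match.arg(metric)
  if (length(reps) < 2 || length(refs) < 2) {
    stop("need at least 2 replicates per setting")
  }
  f <- if (metric == "kl") kl_divergence else bhattacharyya
  tot <- 0
  for (p in reps) for (q in refs) tot <- tot + f(p, q, cap = cap)
  tot / (length(reps) * length(refs))
}

#' Per-gene binned expression distributions
#'
#' Histograms of log2 expression levels on a fixed equal-width binning
#' (default 50 bins spanning the pooled range of the reference states),
#' so that replicate ensembles are compared on a shared support.
#'
#' @param states Log2 expression matrix ([expression_matrix()]).
#' @param breaks Bin edges; computed from `states` when `NULL`.
#' @param n_bins Number of equal-width bins when computing breaks.
#' @return List with `breaks` and `probs`, a genes x bins matrix of
#'   probabilities (values outside the break range are counted into the
#'   nearest edge bin).
#' @export
expression_distributions <- function(states, breaks = NULL, n_bins = 50) {
  m <- as.matrix(states)
  if (is.null(breaks)) breaks <- seq(min(m), max(m), length.out = n_bins + 1L)
  nb <- length(breaks) - 1L
  probs <- t(apply(m, 2, function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), nb)
    tabulate(idx, nbins = nb) / length(x)
  }))
  rownames(probs) <- colnames(m)
  list(breaks = breaks, probs = probs)
}

#' Minimal converged simulation setting on a scanned grid
#'
#' Given dissimilarities measured on an increasing grid of a simulation
#' setting (number of initial conditions or of models), the minimal
#' setting is the smallest one from which increasing the setting further
#' decreases the dissimilarity by less than `threshold`.
#'
#' @param settings Increasing numeric grid (e.g. nIC values).
#' @param dissimilarities Dissimilarity at each setting.
#' @param threshold Decrease regarded as converged (default 5e-4).
#' @return The minimal setting, or `NA` if the decrease never falls below
#'   the threshold ("not reached").
#' @export
minimal_setting_scan <- function(settings, dissimilarities,
                                 threshold = 5e-4) {
  stopifnot(length(settings) == length(dissimilarities),
            length(settings) >= 2, !is.unsorted(settings))
  dec <- -diff(dissimilarities)
  i <- which(dec < threshold)
  if (!length(i)) return(NA_real_)
  settings[i[1]]
}

#' Differentiated model parameters between two gene states
#'
#' Compares, parameter by parameter, the models contributing stable
#' states to cluster `a` against those contributing to cluster `b`: a
#' standardized mean difference (Cohen's d), a rank-based two-sample test
#' (Wilcoxon), and Benjamini-Hochberg adjustment across parameters.  A
#' model contributing states to both clusters appears in both groups.
#'
#' @param ensemble A `racipe_ensemble`.
#' @param labels Cluster label per row of `ensemble$states` (e.g. from
#'   [hierarchical_clusters()]).
#' @param a,b The two cluster labels to contrast.
#' @return A tibble with columns `parameter`, `effect` (standardized
#'   difference, a minus b), `statistic`, `p_value`, `p_adjusted`, sorted
#'   as the parameters; attribute `small_groups` flags groups with fewer
#'   than 5 models.
#' @export
parameter_differentiation <- function(ensemble, labels, a, b) {
  stopifnot(inherits(ensemble, "racipe_ensemble"),
            length(labels) == nrow(ensemble$states))
  models_a <- unique(ensemble$states$model[labels == a])
  models_b <- unique(ensemble$states$model[labels == b])
  if (!length(models_a) || !length(models_b)) {
    stop("both clusters must be non-empty")
  }
  small <- length(models_a) < 5 || length(models_b) < 5
  if (small) {
    warning("a cluster has fewer than 5 contributing models; ",
            "effects are unreliable")
  }
  pars <- ensemble$ranges$parameter
  pa <- ensemble$params[match(models_a, ensemble$params$model), pars,
                        drop = FALSE]
  pb <- ensemble$params[match(models_b, ensemble$params$model), pars,
                        drop = FALSE]
  res <- purrr::map_dfr(pars, function(nm) {
    x <- pa[[nm]]; y <- pb[[nm]]
    sp <- sqrt((stats::var(x) * (length(x) - 1) +
                  stats::var(y) * (length(y) - 1)) /
                 (length(x) + length(y) - 2))
    eff <- if (isTRUE(sp > 0)) (mean(x) - mean(y)) / sp else 0
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    tibble::tibble(parameter = nm, effect = eff,
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  })
  res$p_value[is.na(res$p_value)] <- 1
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  attr(res, "small_groups") <- small
  res
}
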