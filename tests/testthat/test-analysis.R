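test_that("normalization z-scores the pooled states and is invertible", {
  set.seed(1)
  m <- matrix(rnorm(600, mean = 3, sd = 2), 100, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  z <- normalize_expressions(m)
  expect_equal(unname(colMeans(z)), rep(0, 6))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6))
  back <- sweep(sweep(z, 2, attr(z, "scale"), `*`), 2, attr(z, "center"), `+`)
  expect_equal(back, m, ignore_attr = TRUE)
})

test_that("zero-variance genes are rejected by name, and reference
           normalization fixes a knocked-out gene at a constant z", {
  m <- cbind(g1 = rnorm(50), dead = rep(log2(1e-10), 50))
  expect_error(normalize_expressions(m), "dead")
  # with wild-type center/scale the constant column maps to one z value
  z <- normalize_expressions(m, center = c(0, 0), scale = c(1, 4))
  expect_equal(unname(z[, "dead"]), rep(log2(1e-10) / 4, 50))
})

test_that("clustering recovers well-separated groups and their fractions", {
  set.seed(2)
  truth <- rep(1:2, c(120, 80))
  blob <- matrix(rnorm(200 * 10, sd = 0.4), 200, 10) +
    outer(truth == 2, rep(4, 10))
  colnames(blob) <- paste0("g", 1:10)
  cl <- hierarchical_clusters(scale(blob), cutoff = 0.05)
  expect_equal(cl$n_major, 2L)
  # labels match ground truth up to permutation
  tab <- table(cl$labels[cl$labels %in%
                           cl$sizes$cluster[cl$sizes$major]], truth)
  expect_equal(sum(apply(tab, 2, max)), 200)
  expect_equal(sum(cl$sizes$fraction), 1)

  # duplicate rows sit at distance zero and always co-cluster
  dup <- blob[c(1, 1, 1, 50, 50), ]
  cld <- hierarchical_clusters(dup, cutoff = 0.2)
  expect_equal(cld$labels[1], cld$labels[2])
  expect_equal(cld$labels[1], cld$labels[3])
})

test_that("PCA is deterministic in sign and orthogonally reconstructs", {
  set.seed(3)
  m <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("g", 1:6)))
  z <- normalize_expressions(m)
  p <- racipe_pca(z)
  # sign convention: the largest-|loading| entry of each component is +
  for (j in seq_len(ncol(p$rotation))) {
    v <- p$rotation[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # full reconstruction from all components
  recon <- as.matrix(p$scores) %*% t(p$rotation)
  expect_equal(recon, unclass(z)[, ], ignore_attr = TRUE)

  # a state differing only in one gene moves only along that gene's
  # loadings when projected
  z1 <- z[1, , drop = FALSE]
  z2 <- z1
  z2[1, "g3"] <- z2[1, "g3"] - 5
  d <- as.matrix(project_states(p, z2)) - as.matrix(project_states(p, z1))
  expect_equal(as.numeric(d), -5 * p$rotation["g3", ], ignore_attr = TRUE)
})

test_that("state-count distributions normalize and keep the bookkeeping", {
  counts <- c(1, 1, 2, 3, 1, 2, 0)
  d <- state_count_distribution(counts)
  expect_equal(sum(d$prob), 1)
  expect_equal(d$prob[d$n_states == 1], 3 / 7)
  # mean of the distribution times nRM is the total number of states
  expect_equal(sum(d$n_states * d$prob) * length(counts), sum(counts))
  # degenerate: all monostable
  d1 <- state_count_distribution(rep(1L, 10))
  expect_equal(d1$prob, c(0, 1))
  # a fixed support allows cross-ensemble comparison
  d2 <- state_count_distribution(counts, max_count = 5)
  expect_equal(nrow(d2), 6L)
})

test_that("Bhattacharyya distance matches its closed forms", {
  expect_equal(bhattacharyya(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(bhattacharyya(c(1, 0), c(0.5, 0.5)), -log(sqrt(0.5)))
  # symmetry
  set.seed(4)
  p <- prop.table(runif(6)); q <- prop.table(runif(6))
  expect_equal(bhattacharyya(p, q), bhattacharyya(q, p))
  # disjoint support hits the cap
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 700)
  expect_error(bhattacharyya(c(0.5, 0.2), q[1:2]), "normalized")

  # the alternative metric: non-negative, zero iff equal
  expect_equal(kl_divergence(p, p), 0)
  expect_gt(kl_divergence(p, q), 0)
  expect_equal(kl_divergence(c(1, 0), c(0, 1)), 700)
})

test_that("replicate dissimilarity equals the brute-force pairwise average", {
  set.seed(5)
  reps <- lapply(1:3, function(i) prop.table(runif(4)))
  refs <- lapply(1:3, function(i) prop.table(runif(4)))
  brute <- mean(outer(seq_along(reps), seq_along(refs),
                      Vectorize(function(j, h)
                        bhattacharyya(reps[[j]], refs[[h]]))))
  expect_equal(replicate_dissimilarity(reps, refs), brute)
  # identical replicate sets: zero
  same <- lapply(1:3, function(i) c(0.25, 0.75))
  expect_equal(replicate_dissimilarity(same, same), 0)
  expect_error(replicate_dissimilarity(reps[1], refs), "2 replicates")
  # works on state-count tibbles with shared support
  tibs <- lapply(list(c(2, 1, 1), c(1, 1, 2), c(3, 1, 2)),
                 state_count_distribution, max_count = 3)
  vecs <- lapply(tibs, function(x) x$prob)
  expect_equal(replicate_dissimilarity(tibs, tibs),
               replicate_dissimilarity(vecs, vecs))
})

test_that("expression histograms share support and sum to one per gene", {
  set.seed(6)
  m <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("g", 1:4)))
  h <- expression_distributions(m, n_bins = 50)
  expect_equal(dim(h$probs), c(4L, 50L))
  expect_equal(unname(rowSums(h$probs)), rep(1, 4))
  # values beyond the reference breaks land in the edge bins
  h2 <- expression_distributions(m + 100, breaks = h$breaks)
  expect_equal(unname(h2$probs[, 50]), rep(1, 4))
})

test_that("the minimal-setting scan picks the first sub-threshold decrease", {
  grid <- c(10, 50, 100, 500, 1000)
  # strictly flat: first grid point
  expect_equal(minimal_setting_scan(grid, rep(0.3, 5)), 10)
  # one sub-threshold step at 100 -> 500
  expect_equal(
    minimal_setting_scan(grid, c(0.1, 0.05, 0.01, 0.0099, 0.002)), 100)
  # never converging: sentinel
  expect_true(is.na(minimal_setting_scan(grid, c(0.5, 0.4, 0.3, 0.2, 0.1),
                                         threshold = 1e-6)))
})

test_that("parameter differentiation is calibrated under the null and
           finds the toggle's inhibition asymmetry", {
  # null: random labels on one ensemble; adjusted significance ~uniform
  topo <- toggle_topo()
  ens <- run_ensemble(topo, n_models = 800, n_inits = 20, seed = 23)
  set.seed(7)
  labels <- sample(1:2, nrow(ens$states), replace = TRUE)
  null <- parameter_differentiation(ens, labels, 1, 2)
  expect_lte(mean(null$p_adjusted < 0.05), 0.10)

  # identical clusters: zero effects
  same <- parameter_differentiation(ens, rep(1, nrow(ens$states)), 1, 1)
  expect_equal(same$effect, rep(0, nrow(same)))

  # contrast A-high vs B-high monostable models: models locked A-high
  # have a weaker effective inhibition of A by B (B's threshold on A is
  # high, so A's level rarely crosses it) and a stronger production of A
  mono <- ens$params$n_states[ens$states$model] == 1
  a_high <- mono & ens$states$A > ens$states$B
  b_high <- mono & ens$states$B > ens$states$A
  labels2 <- ifelse(a_high, 1L, ifelse(b_high, 2L, 0L))
  diffd <- parameter_differentiation(ens, labels2, 1, 2)
  get <- function(col, nm) diffd[[col]][diffd$parameter == nm]
  expect_gt(get("effect", "Trd_of_BToA"), 0)
  expect_lt(get("p_adjusted", "Trd_of_BToA"), 0.05)
  expect_gt(get("effect", "Prod_of_A"), 0)
  expect_lt(get("p_adjusted", "Prod_of_A"), 0.05)
  # and the mirrored direction for the other toggle arm
  expect_lt(get("effect", "Trd_of_AToB"), 0)
  expect_lt(get("effect", "Prod_of_B"), 0)
})

test_that("small clusters trigger the reliability warning", {
  ens <- run_ensemble(toggle_topo(), n_models = 20, n_inits = 10, seed = 31)
  labels <- rep(2, nrow(ens$states))
  labels[1:2] <- 1
  expect_warning(parameter_differentiation(ens, labels, 1, 2), "fewer than 5")
})
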