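test_that("initial conditions are log-uniform inside the level bounds", {
  topo <- toggle_topo()
  p <- symmetric_toggle_params()
  b <- level_bounds(p, topo)   # [lambda G/k, G/k] = [1, 100] per gene
  expect_equal(b$min, c(1, 1))
  expect_equal(b$max, c(100, 100))
  set.seed(8)
  x <- sample_initial_conditions(p, topo, 1e4)
  expect_true(all(x >= 1 & x <= 100))
  # log-uniform: the sample median sits at the geometric mean of the bounds
  expect_equal(median(x[, 1]), sqrt(1 * 100), tolerance = 0.05)

  # a degenerate interval (unregulated gene) collapses to G/k exactly
  topo1 <- single_link_topo()
  p1 <- c(Prod_of_R = 30, Deg_of_R = 0.5, Prod_of_T = 10, Deg_of_T = 1,
          Trd_of_RToT = 10, Num_of_RToT = 2, Fld_of_RToT = 0.1)
  ic <- sample_initial_conditions(p1, topo1, 5)
  expect_equal(unname(ic[, "R"]), rep(60, 5))
})

test_that("a single unregulated gene relaxes to G/k", {
  # analytically dX/dt = G - kX from any start
  topo1 <- single_link_topo()
  p1 <- c(Prod_of_R = 37, Deg_of_R = 0.4, Prod_of_T = 10, Deg_of_T = 1,
          Trd_of_RToT = 1e9, Num_of_RToT = 1, Fld_of_RToT = 1)
  for (start in c(0.01, 1, 500)) {
    out <- integrate_to_steady(p1, topo1, c(R = start, T = start))
    expect_true(out$converged)
    expect_equal(unname(out$state["R"]), 37 / 0.4, tolerance = 1e-4)
  }
})

test_that("the symmetric strong toggle switch is bistable with mirrored states", {
  topo <- toggle_topo()
  p <- symmetric_toggle_params()
  hi <- integrate_to_steady(p, topo, c(A = 90, B = 0.1))
  lo <- integrate_to_steady(p, topo, c(A = 0.1, B = 90))
  expect_true(hi$converged && lo$converged)
  expect_gt(hi$state["A"], 90)
  expect_lt(hi$state["B"], 2)
  # mirror symmetry
  expect_equal(unname(hi$state["A"]), unname(lo$state["B"]), tolerance = 1e-5)
  expect_equal(unname(hi$state["B"]), unname(lo$state["A"]), tolerance = 1e-5)
})

test_that("euler and rk4 agree on converged steady states", {
  topo <- topo_cts("I", 2)
  ranges <- quick_ranges(topo)
  set.seed(21)
  cfg_rk <- solver_config("rk4")
  cfg_eu <- solver_config("euler")
  for (rep in 1:5) {
    p <- unlist(sample_parameters(ranges, 1))
    init <- sample_initial_conditions(p, topo, 1)
    a <- integrate_to_steady(p, topo, init[1, ], cfg_rk)
    b <- integrate_to_steady(p, topo, init[1, ], cfg_eu)
    expect_true(a$converged && b$converged)
    dlog <- abs(log2(pmax(a$state, 1e-10)) - log2(pmax(b$state, 1e-10)))
    expect_lt(max(dlog), 10 * cfg_rk$conv_tol)
  }
})

test_that("an exhausted window budget is reported as non-convergence", {
  topo1 <- single_link_topo()
  p1 <- c(Prod_of_R = 100, Deg_of_R = 0.1, Prod_of_T = 10, Deg_of_T = 0.1,
          Trd_of_RToT = 10, Num_of_RToT = 2, Fld_of_RToT = 0.1)
  cfg <- solver_config(max_windows = 1)
  out <- integrate_to_steady(p1, topo1, c(R = 0.01, T = 0.01), cfg)
  expect_false(out$converged)
})

test_that("solver configuration validates its invariants", {
  expect_error(solver_config(dt = -1), "dt")
  expect_error(solver_config(dt = 10, t_window = 50))
  expect_error(solver_config(conv_tol = 0))
  expect_identical(solver_config("euler")$dt, 0.01)
  expect_identical(solver_config("rk4")$dt, 0.1)
})

test_that("deduplication is greedy, order-preserving and multiplicity-invariant", {
  one <- matrix(c(10, 20), 1)
  many <- one[rep(1, 1000), ]
  expect_equal(nrow(deduplicate_states(many, 1)), 1L)
  expect_equal(deduplicate_states(many, 1), one, ignore_attr = TRUE)

  # two states 10 log2 units apart in one gene stay distinct at tol 1
  st <- rbind(c(2^0, 16), c(2^10, 16))
  expect_equal(nrow(deduplicate_states(st, 1)), 2L)

  # empty input passes through
  expect_equal(nrow(deduplicate_states(matrix(numeric(), 0, 3), 1)), 0L)
})

test_that("greedy dedup matches the brute-force oracle on small inputs", {
  # oracle: first-occurrence greedy scan written independently on the
  # log2 matrix, checked over random small state sets
  greedy_oracle <- function(lg, tol) {
    kept <- list()
    keep_idx <- integer()
    for (i in seq_len(nrow(lg))) {
      if (all(vapply(kept, function(v) sqrt(sum((v - lg[i, ])^2)) > tol,
                     logical(1)))) {
        kept[[length(kept) + 1L]] <- lg[i, ]
        keep_idx <- c(keep_idx, i)
      }
    }
    keep_idx
  }
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    st <- matrix(2^stats::runif(2 * n, -2, 8), n, 2)
    tol <- stats::runif(1, 0.3, 3)
    got <- deduplicate_states(st, tol)
    idx <- greedy_oracle(log2(st), tol)
    expect_equal(got, st[idx, , drop = FALSE], ignore_attr = TRUE)
    # kept states are pairwise separated beyond tol
    lg <- log2(got)
    if (nrow(lg) > 1) {
      d <- as.matrix(stats::dist(lg))
      expect_true(all(d[upper.tri(d)] > tol))
    }
  }
})

test_that("toggle-switch models have between 0 and 3 stable states", {
  ens <- run_ensemble(toggle_topo(), n_models = 1000, n_inits = 20, seed = 17)
  expect_true(all(ens$params$n_states %in% 0:3))
  expect_gt(mean(ens$params$n_states == 2), 0)   # some bistable models
  expect_gt(mean(ens$params$n_states == 1), 0)   # some monostable models
})

test_that("attractor sets match an independent adaptive integrator", {
  skip_if_not_installed("deSolve")
  topo <- topo_cts("I", 2)
  ranges <- quick_ranges(topo)
  cfg <- solver_config()
  rhs <- function(t, x, p) {
    list(as.numeric(circuit_derivatives(pmax(x, 0), p, topo)))
  }
  set.seed(41)
  for (rep in 1:3) {
    p <- unlist(sample_parameters(ranges, 1))
    inits <- sample_initial_conditions(p, topo, 40)
    out <- racipe:::integrate_states(p, topo, inits, cfg)
    st <- out$states[out$converged, , drop = FALSE]
    ours <- deduplicate_states(st, cfg$dedup_tol)
    ref_fin <- t(apply(inits, 1, function(x0) {
      o <- deSolve::lsoda(x0, c(0, 2000, 4000), rhs, p,
                          rtol = 1e-8, atol = 1e-8)
      o[nrow(o), -1]
    }))
    ref <- deduplicate_states(pmax(ref_fin, 0), cfg$dedup_tol)
    expect_equal(nrow(ours), nrow(ref))
    # every state found has a near-identical partner in the reference set
    lo <- log2(pmax(ours, 1e-10)); lr <- log2(pmax(ref, 1e-10))
    for (r in seq_len(nrow(lo))) {
      dmin <- min(sqrt(rowSums((lr - matrix(lo[r, ], nrow(lr), ncol(lr),
                                            byrow = TRUE))^2)))
      expect_lt(dmin, 0.05)
    }
  }
})
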