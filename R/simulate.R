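LEVEL_FLOOR <- 1e-10  # levels below this are indistinguishable from zero
IC_FLOOR <- 1e-8      # positive floor for log-uniform initial sampling

#' Solver configuration
#'
#' Controls the fixed-step integration used to relax each initial
#' condition to a stable steady state, and the deduplication of the states
#' found.  Integration proceeds in windows of `t_window` time units; a run
#' is converged once the largest per-gene change in log2 level over one
#' window drops below `conv_tol`.  Both solvers share the same fixed
#' points (a state with zero derivative is stationary under either map),
#' so the method/step choice trades stability against cost, not accuracy
#' of the steady state itself.
#'
#' @param method `"rk4"` (classical Runge-Kutta, default) or `"euler"`.
#' @param dt Time step; defaults to 0.1 for rk4 and 0.01 for euler.
#' @param t_window Time per convergence check (>= 10 * dt).
#' @param max_windows Window cap before a start is declared non-converged.
#' @param conv_tol Convergence tolerance, max |delta log2 level| per window.
#' @param dedup_tol Euclidean distance in log2 space below which two
#'   steady states of one model are considered the same state.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(method = c("rk4", "euler"), dt = NULL,
                          t_window = 50, max_windows = 200,
                          conv_tol = 1e-3, dedup_tol = 1) {
  method <- match.arg(method)
  if (is.null(dt)) dt <- if (method == "rk4") 0.1 else 0.01
  stopifnot(dt > 0, t_window >= 10 * dt, max_windows >= 1,
            conv_tol > 0, dedup_tol > 0)
  structure(list(method = method, dt = dt, t_window = t_window,
                 max_windows = max_windows, conv_tol = conv_tol,
                 dedup_tol = dedup_tol),
            class = "solver_config")
}

#' Sample initial conditions log-uniformly between the level bounds
#'
#' Each gene's initial level is drawn log-uniformly between its minimum
#' and maximum possible steady levels (see [level_bounds()]), floored at a
#' small positive constant; a degenerate interval (an unregulated gene)
#' yields its `G/k` level exactly.
#'
#' @inheritParams circuit_derivatives
#' @param n Number of initial conditions.
#' @return An `n` by `n_genes` matrix of positive levels, columns in gene
#'   order.
#' @export
sample_initial_conditions <- function(params, topology, n = 1) {
  b <- level_bounds(params, topology)
  lo <- log(pmax(b$min, IC_FLOOR))
  hi <- log(pmax(b$max, IC_FLOOR))
  u <- matrix(stats::runif(n * length(lo)), nrow = n)
  x <- exp(sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
  colnames(x) <- topology$genes
  x
}

# Dispatch one model's initial-condition matrix to the compiled integrator.
integrate_states <- function(params, topology, inits,
                             cfg = solver_config()) {
  if (is.data.frame(params)) params <- unlist(params[1, param_names(topology)])
  ar <- param_arrays(params, topology)
  steps <- max(1L, as.integer(round(cfg$t_window / cfg$dt)))
  cpp_integrate_states(ar$G, ar$k, ar$src, ar$tgt, ar$b0, ar$n,
                       ar$hill_a, ar$hill_b,
                       inits, if (cfg$method == "euler") 0L else 1L,
                       cfg$dt, steps, cfg$max_windows, cfg$conv_tol)
}

#' Integrate one initial condition to a stable steady state
#'
#' @inheritParams circuit_derivatives
#' @param init Non-negative initial expression vector.
#' @param cfg A [solver_config()].
#' @return A list with `state` (named level vector, `NA` if the run blew
#'   up) and `converged` (logical).  Numerical overflow or an exhausted
#'   window budget is reported as non-convergence, never as an error.
#' @export
integrate_to_steady <- function(params, topology, init,
                                cfg = solver_config()) {
  stopifnot(all(init >= 0), length(init) == length(topology$genes))
  out <- integrate_states(params, topology, matrix(as.numeric(init), nrow = 1),
                          cfg)
  st <- out$states[1, ]
  st[!is.na(st) & st < LEVEL_FLOOR] <- 0
  list(state = stats::setNames(st, topology$genes),
       converged = out$converged[1])
}

#' Deduplicate steady states of one model
#'
#' Greedy scan in input order: a state is kept iff its Euclidean distance
#' in log2 space to every already-kept state exceeds `dedup_tol`.  The
#' result is independent of how many duplicates of each state appear, and
#' its order is the first-occurrence order.
#'
#' @param states Matrix of expression levels, one state per row (linear
#'   scale; log2 is taken internally with a floor of `1e-10`).
#' @param dedup_tol Distance threshold in log2 space.
#' @return The kept rows of `states`.
#' @export
deduplicate_states <- function(states, dedup_tol = 1) {
  states <- as.matrix(states)
  if (nrow(states) == 0L) return(states)
  lg <- log2(pmax(states, LEVEL_FLOOR))
  kept <- 1L
  for (i in seq_len(nrow(states))[-1]) {
    d2 <- rowSums((lg[kept, , drop = FALSE] -
                     matrix(lg[i, ], nrow = length(kept), ncol = ncol(lg),
                            byrow = TRUE))^2)
    if (all(d2 > dedup_tol^2)) kept <- c(kept, i)
  }
  states[kept, , drop = FALSE]
}

# Full treatment of one model: sample nIC starts, relax each, keep the
# distinct stable states.  Sub-floor levels are snapped to exact zero.
simulate_model <- function(params, topology, n_inits,
                           cfg = solver_config()) {
  inits <- sample_initial_conditions(params, topology, n_inits)
  out <- integrate_states(params, topology, inits, cfg)
  conv <- out$converged
  states <- out$states[conv, , drop = FALSE]
  states[states < LEVEL_FLOOR] <- 0
  states <- deduplicate_states(states, cfg$dedup_tol)
  colnames(states) <- topology$genes
  list(states = states, n_unconverged = sum(!conv))
}
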