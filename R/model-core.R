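#' Shifted Hill regulatory response
#'
#' The shifted Hill function rescales the inhibitory Hill response
#' \eqn{H^-(X) = 1 / (1 + (X/X_0)^n)} so that its dynamic range runs from 1
#' (no regulator) to the fold change \eqn{\lambda}:
#' \deqn{H^S(X) = \lambda + (1 - \lambda) H^-(X).}
#' Inhibition uses \eqn{\lambda < 1} (response falls from 1 to
#' \eqn{\lambda}); activation uses the same form with \eqn{\lambda > 1}
#' (response rises from 1 to \eqn{\lambda}).  \eqn{\lambda = 1} is the
#' no-regulation identity.
#'
#' @param x Regulator level(s), >= 0.
#' @param x0 Threshold level, > 0.
#' @param n Hill coefficient, >= 1 (real values accepted).
#' @param lambda Maximum fold change, > 0.
#' @return Dimensionless multiplicative factor(s), bounded between
#'   `min(1, lambda)` and `max(1, lambda)`.
#' @examples
#' shifted_hill(0, 10, 4, 0.1)    # 1: no regulator bound
#' shifted_hill(10, 10, 4, 0.1)   # (1 + 0.1) / 2: half occupancy
#' @export
shifted_hill <- function(x, x0, n, lambda) {
  if (any(x0 <= 0)) stop("threshold x0 must be positive")
  lambda + (1 - lambda) / (1 + (x / x0)^n)
}

# Canonical parameter vector layout: for every gene (topology order) its
# production and degradation rate, then for every edge (file order) its
# threshold, Hill coefficient and fold change.  This order defines the
# `.prs` file and the columns of `<prefix>_parameter.dat`.
param_names <- function(topology) {
  g <- topology$genes
  e <- topology$edges
  ename <- paste0(e$source, "To", e$target)
  c(as.vector(rbind(paste0("Prod_of_", g), paste0("Deg_of_", g))),
    as.vector(rbind(paste0("Trd_of_", ename),
                    paste0("Num_of_", ename),
                    paste0("Fld_of_", ename))))
}

# Split a canonical parameter vector into the arrays the right-hand side
# consumes: per-gene G, k and per-edge b0, n, lambda.
#
# The regulatory factor of every edge is affine in the inhibitory Hill
# response, factor = a + b * H^-(X):
#   inhibition: a = lambda,  b = 1 - lambda    (falls from 1 to lambda)
#   activation: a = 1,       b = 1/lambda - 1  (rises from 1/lambda to 1)
# The activation form is the shifted Hill response divided by lambda, so
# that G is the production rate with all activators bound (its defined
# meaning) and the basal rate without the activator is G/lambda.
param_arrays <- function(params, topology) {
  params <- as.numeric(params)
  ng <- length(topology$genes)
  ne <- nrow(topology$edges)
  stopifnot(length(params) == 2L * ng + 3L * ne)
  gp <- matrix(params[seq_len(2L * ng)], nrow = 2L)
  ep <- if (ne) matrix(params[-seq_len(2L * ng)], nrow = 3L) else
    matrix(numeric(), nrow = 3L)
  lam <- ep[3, ]
  act <- topology$edges$type == 1L
  a <- ifelse(act, 1, lam)
  b <- ifelse(act, 1 / lam - 1, 1 - lam)
  list(
    G   = stats::setNames(gp[1, ], topology$genes),
    k   = stats::setNames(gp[2, ], topology$genes),
    b0  = ep[1, ],
    n   = ep[2, ],
    lam = lam,
    hill_a = as.numeric(a),
    hill_b = as.numeric(b),
    src = match(topology$edges$source, topology$genes) - 1L,
    tgt = match(topology$edges$target, topology$genes) - 1L
  )
}

#' Rate equations of a randomized circuit model
#'
#' Evaluates the right-hand side of the circuit ODEs: each gene is produced
#' at its maximum rate times the product of the regulatory factors of all
#' its incoming links (regulatory interactions are assumed independent),
#' and degrades linearly:
#' \deqn{dX_i/dt = G_i \prod_{j \to i} F_{ji}(X_j) - k_i X_i.}
#' An inhibitory link contributes the shifted Hill response itself,
#' \eqn{F = H^S \in [\lambda, 1]}; an activating link contributes the
#' normalized response \eqn{F = H^S/\lambda \in [1/\lambda, 1]}, so that
#' \eqn{G_i} keeps its defined meaning of the production rate with all
#' activators (and no inhibitor) bound, and the basal rate without an
#' activator is \eqn{G_i/\lambda}.
#'
#' @param state Numeric vector of expression levels, ordered as
#'   `topology$genes`.
#' @param params Parameter vector in canonical order (see
#'   [build_parameter_ranges()]), or a one-row data frame of it.
#' @param topology A [circuit_topology()].
#' @return Named numeric vector of time derivatives.
#' @export
circuit_derivatives <- function(state, params, topology) {
  stopifnot(inherits(topology, "circuit_topology"))
  if (is.data.frame(params)) params <- unlist(params[1, param_names(topology)])
  ar <- param_arrays(params, topology)
  state <- as.numeric(state)
  stopifnot(length(state) == length(topology$genes))
  prod <- ar$G
  ne <- length(ar$src)
  for (e in seq_len(ne)) {
    i <- ar$tgt[e] + 1L
    hminus <- 1 / (1 + (state[ar$src[e] + 1L] / ar$b0[e])^ar$n[e])
    prod[i] <- prod[i] * (ar$hill_a[e] + ar$hill_b[e] * hminus)
  }
  stats::setNames(prod - ar$k * state, topology$genes)
}

#' Steady-state level bounds of each gene
#'
#' For a given parameter set, every gene's steady level is confined to the
#' interval `G/k` times the product of its incoming links' extreme
#' regulatory factors (`[lambda, 1]` for inhibition, `[1/lambda, 1]` for
#' activation).  These bounds delimit the log-uniform initial-condition
#' sampling.
#'
#' @inheritParams circuit_derivatives
#' @return A tibble with columns `gene`, `min`, `max`.
#' @export
level_bounds <- function(params, topology) {
  if (is.data.frame(params)) params <- unlist(params[1, param_names(topology)])
  ar <- param_arrays(params, topology)
  base <- ar$G / ar$k
  lo <- hi <- rep(1, length(base))
  for (e in seq_along(ar$src)) {
    i <- ar$tgt[e] + 1L
    f <- c(ar$hill_a[e], ar$hill_a[e] + ar$hill_b[e])
    lo[i] <- lo[i] * min(f)
    hi[i] <- hi[i] * max(f)
  }
  tibble::tibble(gene = topology$genes,
                 min = unname(base * lo), max = unname(base * hi))
}
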