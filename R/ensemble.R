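#' Run a randomized-model ensemble for a circuit
#'
#' The core workflow: build (or take) per-parameter randomization ranges,
#' then for each of `n_models` models draw a full kinetic parameter set,
#' relax `n_inits` log-uniform initial conditions to steady state, and
#' record the distinct stable states.  Model `m` uses a random stream
#' derived deterministically from `(seed, m)`, so results are reproducible
#' and, for perturbed ranges with the same row layout (knockout,
#' over/under-expression), model `m` shares all untouched parameter draws
#' with its unperturbed counterpart — a paired design.
#'
#' @param topology A [circuit_topology()].
#' @param n_models Number of randomized models (nRM).
#' @param n_inits Initial conditions per model (nIC).
#' @param cfg A [solver_config()].
#' @param ranges Optional pre-built (possibly perturbed) `racipe_ranges`;
#'   built from `topology` under the run's seed when `NULL`.
#' @param seed Master seed; every random draw in the run derives from it.
#' @param ... Passed to [build_parameter_ranges()] when `ranges` is `NULL`.
#' @return An object of class `racipe_ensemble`: a list with `topology`,
#'   `ranges`, `params` (tibble: `model`, `n_states`, `n_unconverged`,
#'   then one column per parameter), `states` (tibble: `model`, `state`,
#'   then one log2-level column per gene), `n_models`, `n_inits`, `seed`,
#'   `cfg`.
#' @examples
#' ens <- run_ensemble(topo_cts("I", 1), n_models = 20, n_inits = 20, seed = 1)
#' glance(ens)
#' @export
run_ensemble <- function(topology, n_models, n_inits,
                         cfg = solver_config(), ranges = NULL, seed = 1, ...) {
  stopifnot(inherits(topology, "circuit_topology"),
            n_models >= 1, n_inits >= 1)
  # two independent child streams: one for range estimation, one seeding
  # the per-model streams (kept separate so supplying pre-built ranges
  # does not shift the model draws)
  set.seed(seed)
  child <- sample.int(2147483646L, 2L)
  if (is.null(ranges)) {
    set.seed(child[1])
    ranges <- build_parameter_ranges(topology, ...)
  }
  stopifnot(identical(ranges$parameter, param_names(topology)))
  set.seed(child[2])
  model_seeds <- sample.int(2147483646L, n_models)

  npar <- nrow(ranges)
  ngene <- length(topology$genes)
  par_mat <- matrix(NA_real_, n_models, npar)
  n_states <- integer(n_models)
  n_unconv <- integer(n_models)
  state_rows <- vector("list", n_models)

  for (m in seq_len(n_models)) {
    set.seed(model_seeds[m])
    p <- unlist(sample_parameters(ranges, 1))
    par_mat[m, ] <- p
    sim <- simulate_model(p, topology, n_inits, cfg)
    n_states[m] <- nrow(sim$states)
    n_unconv[m] <- sim$n_unconverged
    if (n_states[m] > 0L) {
      state_rows[[m]] <- cbind(model = m, state = seq_len(n_states[m]),
                               log2(pmax(sim$states, LEVEL_FLOOR)))
    }
  }

  params <- tibble::as_tibble(as.data.frame(par_mat))
  names(params) <- ranges$parameter
  params <- dplyr::bind_cols(
    tibble::tibble(model = seq_len(n_models), n_states = n_states,
                   n_unconverged = n_unconv),
    params
  )
  sm <- do.call(rbind, state_rows)
  states <- if (is.null(sm)) {
    tibble::as_tibble(matrix(numeric(), 0, 2 + ngene,
                             dimnames = list(NULL, c("model", "state",
                                                     topology$genes))))
  } else {
    tibble::as_tibble(as.data.frame(sm))
  }

  structure(list(topology = topology, ranges = ranges, params = params,
                 states = states, n_models = as.integer(n_models),
                 n_inits = as.integer(n_inits), seed = seed, cfg = cfg),
            class = "racipe_ensemble")
}

#' @export
print.racipe_ensemble <- function(x, ...) {
  cat("<racipe_ensemble> ", length(x$topology$genes), " genes, ",
      x$n_models, " models x ", x$n_inits, " initial conditions\n", sep = "")
  tab <- table(x$params$n_states)
  cat("stable states per model:\n")
  print(tab)
  cat("total states: ", nrow(x$states), "\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for ensembles
#'
#' `tidy()` returns the stable-state table (one row per state, log2
#' levels); `glance()` a one-row summary of the run.
#'
#' @param x A `racipe_ensemble`.
#' @param ... Unused.
#' @export
tidy.racipe_ensemble <- function(x, ...) {
  x$states
}

#' @rdname tidy.racipe_ensemble
#' @importFrom generics glance
#' @export
glance.racipe_ensemble <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$topology$genes),
    n_models = x$n_models,
    n_inits = x$n_inits,
    total_states = nrow(x$states),
    states_per_model = nrow(x$states) / x$n_models,
    max_states = max(x$params$n_states),
    frac_unconverged = sum(x$params$n_unconverged) /
      (x$n_models * x$n_inits)
  )
}

#' Gene-expression matrix of the pooled stable states
#'
#' @param x A `racipe_ensemble` (or object from [read_ensemble()]).
#' @return Numeric matrix, one row per stable state across all models,
#'   one column per gene, log2 levels.
#' @export
expression_matrix <- function(x) {
  as.matrix(x$states[, x$topology$genes, drop = FALSE])
}

#' Write / read the ensemble output files
#'
#' Serializes a run in the tool's plain-matrix layout under a common file
#' prefix: `<prefix>.prs` (the parameter ranges), `<prefix>_parameter.dat`
#' (one row per model: model index, number of stable states, then the
#' parameters in `.prs` order) and, for every realized state count `i`,
#' `<prefix>_solution_<i>.dat` (one row per model with `i` states: model
#' index, then `i` blocks of per-gene log2 expression levels in discovery
#' order).  `.dat` files are tab-delimited with no header row; lines
#' starting with `#` are comments.
#'
#' @param result A `racipe_ensemble`.
#' @param prefix Path prefix for the output files.
#' @return `write_ensemble()` returns the written paths invisibly;
#'   `read_ensemble()` reconstructs an ensemble object (topology, ranges,
#'   parameters, states) from the files.
#' @export
write_ensemble <- function(result, prefix) {
  stopifnot(inherits(result, "racipe_ensemble"))
  paths <- character()
  prs <- paste0(prefix, ".prs")
  write_prs(result$ranges, prs)
  paths <- prs

  fmt_row <- function(...) paste(c(...), collapse = "\t")
  par_path <- paste0(prefix, "_parameter.dat")
  pm <- as.matrix(result$params[, result$ranges$parameter, drop = FALSE])
  lines <- vapply(seq_len(nrow(pm)), function(m) {
    fmt_row(result$params$model[m], result$params$n_states[m],
            sprintf("%.6g", pm[m, ]))
  }, character(1))
  writeLines(c("# model\tn_states\tparameters (order as in .prs)", lines),
             par_path)
  paths <- c(paths, par_path)

  genes <- result$topology$genes
  counts <- sort(unique(result$params$n_states))
  counts <- counts[counts > 0]
  for (i in counts) {
    sol_path <- paste0(prefix, "_solution_", i, ".dat")
    models <- result$params$model[result$params$n_states == i]
    lines <- vapply(models, function(m) {
      s <- result$states[result$states$model == m, genes, drop = FALSE]
      fmt_row(m, sprintf("%.6g", t(as.matrix(s))))
    }, character(1))
    writeLines(c("# model, then per stable state the log2 expression levels in gene order",
                 lines), sol_path)
    paths <- c(paths, sol_path)
  }
  invisible(paths)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(prefix) {
  ranges <- read_prs(paste0(prefix, ".prs"))
  topology <- topology_from_ranges(ranges)
  genes <- topology$genes

  read_dat <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric)
  }

  rows <- read_dat(paste0(prefix, "_parameter.dat"))
  npar <- nrow(ranges)
  if (length(rows) && any(lengths(rows) != npar + 2L)) {
    stop("parameter file width does not match the .prs parameter count")
  }
  pm <- do.call(rbind, rows)
  params <- if (is.null(pm)) {
    tibble::as_tibble(matrix(numeric(), 0, npar + 2L,
                             dimnames = list(NULL, c("model", "n_states",
                                                     ranges$parameter))))
  } else {
    colnames(pm) <- c("model", "n_states", ranges$parameter)
    tibble::as_tibble(as.data.frame(pm))
  }

  state_rows <- list()
  for (i in sort(unique(params$n_states))) {
    if (i == 0) next
    sol_path <- paste0(prefix, "_solution_", i, ".dat")
    if (!file.exists(sol_path)) {
      stop("missing solution file for state count ", i, ": ", sol_path)
    }
    rows <- read_dat(sol_path)
    if (any(lengths(rows) != 1L + i * length(genes))) {
      stop("solution file ", sol_path, " has rows of the wrong width")
    }
    for (r in rows) {
      lv <- matrix(r[-1], ncol = length(genes), byrow = TRUE)
      state_rows[[length(state_rows) + 1L]] <-
        cbind(model = r[1], state = seq_len(i), lv)
    }
  }
  sm <- do.call(rbind, state_rows)
  states <- if (is.null(sm)) {
    tibble::as_tibble(matrix(numeric(), 0, 2 + length(genes),
                             dimnames = list(NULL, c("model", "state", genes))))
  } else {
    colnames(sm) <- c("model", "state", genes)
    sm <- sm[order(sm[, "model"], sm[, "state"]), , drop = FALSE]
    tibble::as_tibble(as.data.frame(sm))
  }

  structure(list(topology = topology, ranges = ranges, params = params,
                 states = states,
                 n_models = nrow(params), n_inits = NA_integer_,
                 seed = NA_integer_, cfg = NULL),
            class = "racipe_ensemble")
}
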