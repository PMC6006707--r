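#' Build randomization ranges for every kinetic parameter of a circuit
#'
#' Each randomized model draws its parameters independently from
#' per-parameter ranges.  Production and degradation rates, Hill
#' coefficients and fold changes use preset ranges; the threshold of every
#' regulatory link is estimated numerically so that the link is functional
#' in roughly half of the sampled models (the "half-functional" rule, see
#' [estimate_threshold_range()]).
#'
#' Sampling laws: production `G ~ U[1, 100]`, degradation `k ~ U[0.1, 1]`,
#' Hill coefficient `n` uniform on the integers 1..6, activation fold
#' change `lambda ~ U[1, 100]`, inhibition fold change `1/lambda ~ U[1, 100]`
#' (so `lambda` itself is reciprocal-uniform on `[0.01, 1]`).
#'
#' Threshold bounds are rounded to 6 significant digits so that the
#' `.prs` serialization round-trips exactly.
#'
#' @param topology A [circuit_topology()].
#' @param prod_range,deg_range,fold_range Numeric length-2 `[min, max]`
#'   ranges for production, degradation and fold change.
#' @param hill_levels Integer vector of admissible Hill coefficients.
#' @param threshold_window Multipliers `(lo, hi)` applied to the estimated
#'   median regulator level to form the threshold range.
#' @param mc_samples Monte-Carlo sample count for threshold estimation.
#' @return A tibble of class `racipe_ranges` with columns `parameter`,
#'   `min`, `max`, `law` — one row per model parameter, in the canonical
#'   order used by the `.prs` file and the parameter output columns:
#'   `Prod_of_<gene>`, `Deg_of_<gene>` per gene, then
#'   `Trd_of_<src>To<tgt>`, `Num_of_<src>To<tgt>`, `Fld_of_<src>To<tgt>`
#'   per edge.
#' @examples
#' set.seed(1)
#' build_parameter_ranges(topo_cts("I", 1))
#' @export
build_parameter_ranges <- function(topology,
                                   prod_range = c(1, 100),
                                   deg_range = c(0.1, 1),
                                   hill_levels = 1:6,
                                   fold_range = c(1, 100),
                                   threshold_window = c(0.02, 1.98),
                                   mc_samples = 10000) {
  stopifnot(inherits(topology, "circuit_topology"),
            prod_range[1] > 0, diff(prod_range) > 0,
            deg_range[1] > 0, diff(deg_range) > 0,
            fold_range[1] >= 1, diff(fold_range) > 0,
            all(hill_levels >= 1), threshold_window[1] > 0,
            threshold_window[2] > threshold_window[1])
  g <- topology$genes
  e <- topology$edges

  gene_rows <- tibble::tibble(
    parameter = as.vector(rbind(paste0("Prod_of_", g), paste0("Deg_of_", g))),
    min = rep(c(prod_range[1], deg_range[1]), length(g)),
    max = rep(c(prod_range[2], deg_range[2]), length(g)),
    law = "uniform"
  )

  edge_rows <- NULL
  if (nrow(e)) {
    trd <- vapply(seq_len(nrow(e)), function(i) {
      estimate_threshold_range(e[i, ], topology,
                               prod_range = prod_range, deg_range = deg_range,
                               fold_range = fold_range,
                               threshold_window = threshold_window,
                               mc_samples = mc_samples)
    }, numeric(2))
    ename <- paste0(e$source, "To", e$target)
    edge_rows <- tibble::tibble(
      parameter = as.vector(rbind(paste0("Trd_of_", ename),
                                  paste0("Num_of_", ename),
                                  paste0("Fld_of_", ename))),
      min = as.vector(rbind(signif(trd[1, ], 6), min(hill_levels),
                            ifelse(e$type == 1L, fold_range[1],
                                   1 / fold_range[2]))),
      max = as.vector(rbind(signif(trd[2, ], 6), max(hill_levels),
                            ifelse(e$type == 1L, fold_range[2],
                                   1 / fold_range[1]))),
      law = as.vector(rbind("uniform", "int_uniform",
                            ifelse(e$type == 1L, "uniform",
                                   "reciprocal_uniform")))
    )
  }

  ranges <- dplyr::bind_rows(gene_rows, edge_rows)
  class(ranges) <- c("racipe_ranges", class(ranges))
  ranges
}

#' Estimate a half-functional threshold range for one regulatory link
#'
#' A link is functional in a model when its regulator's level crosses the
#' link's threshold, i.e. the shifted-Hill factor deviates from 1 by more
#' than half its maximum deviation.  To give each link about a 50% chance
#' of being functional across the ensemble, the threshold range is centred
#' on the Monte-Carlo median `M` of the regulator's standalone steady
#' level: draw `G ~ U[prod_range]`, `k ~ U[deg_range]` and, for every link
#' incoming to the regulator, an independent regulatory factor uniform
#' between its extreme values — `[lambda, 1]` for an inhibitor and
#' `[1/lambda, 1]` for an activator (the lambda-normalized response), with
#' `lambda` drawn from its own sampling law (one level of regulatory
#' context, no fixed-point self-consistency); the level is `(G/k)` times
#' the product of the factors.  The returned range is
#' `(threshold_window[1] * M, threshold_window[2] * M)`, symmetric about
#' `M` for the default `(0.02, 1.98)` window.
#'
#' @param edge One-row data frame with `source`, `target`, `type`.
#' @param topology The circuit the edge belongs to (supplies the
#'   regulator's incoming links).
#' @inheritParams build_parameter_ranges
#' @return Numeric `c(min, max)` threshold interval.
#' @export
estimate_threshold_range <- function(edge, topology,
                                     prod_range = c(1, 100),
                                     deg_range = c(0.1, 1),
                                     fold_range = c(1, 100),
                                     threshold_window = c(0.02, 1.98),
                                     mc_samples = 10000) {
  if (mc_samples < 1000) {
    stop("mc_samples must be >= 1000: the median estimate is too noisy below that")
  }
  reg <- edge$source[[1]]
  stopifnot(reg %in% topology$genes)
  level <- stats::runif(mc_samples, prod_range[1], prod_range[2]) /
    stats::runif(mc_samples, deg_range[1], deg_range[2])
  incoming <- which(topology$edges$target == reg)
  for (i in incoming) {
    # extreme regulatory factors: [1/lambda, 1] for an activator (the
    # lambda-normalized response), [lambda, 1] for an inhibitor
    lam <- 1 / stats::runif(mc_samples, fold_range[1], fold_range[2])
    level <- level * stats::runif(mc_samples, lam, 1)
  }
  m <- stats::median(level)
  threshold_window * m
}

#' Sample complete parameter sets from randomization ranges
#'
#' Every parameter is drawn independently according to its law: `uniform`
#' on `[min, max]`; `int_uniform` on the integers `min..max`;
#' `reciprocal_uniform` as the reciprocal of a uniform draw on
#' `[1/max, 1/min]` (used for inhibitory fold changes, so strong and weak
#' inhibition are equally represented on the reciprocal scale).
#'
#' @param ranges A `racipe_ranges` tibble from [build_parameter_ranges()].
#' @param n Number of parameter sets to draw.
#' @return A tibble with `n` rows and one column per parameter, columns in
#'   canonical range order.
#' @export
sample_parameters <- function(ranges, n = 1) {
  stopifnot(is.data.frame(ranges), n >= 1)
  # every parameter consumes exactly n stream draws, including degenerate
  # (e.g. knocked-out) ranges, so that perturbed and unperturbed runs of
  # the same seed stay paired on every untouched parameter
  draws <- purrr::pmap(ranges[, c("min", "max", "law")],
    function(min, max, law) {
      u <- stats::runif(n)
      switch(law,
        uniform = min + (max - min) * u,
        int_uniform = pmin(floor(min + (max - min + 1) * u), max),
        reciprocal_uniform = 1 / (1 / max + (1 / min - 1 / max) * u),
        stop("unknown sampling law: ", law)
      )
    })
  names(draws) <- ranges$parameter
  tibble::as_tibble(draws)
}

#' Read / write parameter-range (`.prs`) files
#'
#' Tab-delimited with header `Parameter Minimum Maximum`, one row per
#' parameter in canonical order, 6 significant digits.  The sampling law
#' is implied by the parameter name and range (`Num_of_*` are integer
#' uniform; `Fld_of_*` with `max <= 1` are reciprocal uniform).
#'
#' @param ranges A `racipe_ranges` tibble.
#' @param path Output file path.
#' @return `write_prs()` returns `path` invisibly; `read_prs()` returns a
#'   `racipe_ranges` tibble.
#' @export
write_prs <- function(ranges, path) {
  lines <- c("Parameter\tMinimum\tMaximum",
             sprintf("%s\t%.6g\t%.6g", ranges$parameter, ranges$min, ranges$max))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_prs
#' @export
read_prs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stopifnot(length(lines) >= 1L,
            grepl("^Parameter\tMinimum\tMaximum$", lines[1]))
  lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 3L))
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  ranges <- tibble::tibble(
    parameter = m[, 1],
    min = as.numeric(m[, 2]),
    max = as.numeric(m[, 3])
  )
  ranges$law <- dplyr::case_when(
    startsWith(ranges$parameter, "Num_of_") ~ "int_uniform",
    startsWith(ranges$parameter, "Fld_of_") & ranges$max <= 1 ~
      "reciprocal_uniform",
    TRUE ~ "uniform"
  )
  class(ranges) <- c("racipe_ranges", class(ranges))
  ranges
}

# Reconstruct the circuit a `.prs` file (or ranges tibble) describes: gene
# order from Prod_of_ rows, edges from Trd_of_ rows, the interaction type
# from the fold-change range (max <= 1 means inhibition).
topology_from_ranges <- function(ranges) {
  genes <- sub("^Prod_of_", "",
               ranges$parameter[startsWith(ranges$parameter, "Prod_of_")])
  trd <- ranges$parameter[startsWith(ranges$parameter, "Trd_of_")]
  fld <- ranges[startsWith(ranges$parameter, "Fld_of_"), ]
  if (!length(trd)) stop("ranges describe a circuit with no edges")
  pair <- sub("^Trd_of_", "", trd)
  src <- tgt <- character(length(pair))
  for (i in seq_along(pair)) {
    # split on the unique 'To' that separates two known gene names
    hit <- NULL
    for (g in genes[order(nchar(genes), decreasing = TRUE)]) {
      if (startsWith(pair[i], paste0(g, "To")) &&
          substring(pair[i], nchar(g) + 3L) %in% genes) {
        hit <- g
        break
      }
    }
    if (is.null(hit)) stop("cannot parse edge name: ", pair[i])
    src[i] <- hit
    tgt[i] <- substring(pair[i], nchar(hit) + 3L)
  }
  type <- ifelse(fld$max <= 1, 2L, 1L)
  topo <- circuit_topology(tibble::tibble(source = src, target = tgt,
                                          type = type))
  if (!setequal(topo$genes, genes)) {
    stop("gene set implied by edges does not match Prod_of_ rows")
  }
  topo$genes <- genes
  topo
}
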