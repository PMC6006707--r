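#' In-silico circuit perturbations
#'
#' Constructs a perturbation specification to apply to a circuit and its
#' randomization ranges before ensemble generation: gene knockout
#' (production pinned to zero, so the gene's level is 0 and its outgoing
#' links sit at their no-regulator value), over-expression / knockdown
#' (the production range scaled by a factor), or removal of a single
#' regulatory link.
#'
#' @param kind One of `"knockout"`, `"overexpress"`, `"knockdown"`,
#'   `"remove_link"`.
#' @param target Gene name, or `c(source, target)` for `"remove_link"`.
#' @param factor Positive production scale for over/under-expression
#'   (default 10 for overexpress, 0.1 for knockdown).
#' @return A list of class `perturbation`.
#' @examples
#' perturbation("knockout", "A1")
#' perturbation("overexpress", "B2", factor = 10)
#' @export
perturbation <- function(kind = c("knockout", "overexpress", "knockdown",
                                  "remove_link"),
                         target, factor = NULL) {
  kind <- match.arg(kind)
  if (is.null(factor)) {
    factor <- switch(kind, overexpress = 10, knockdown = 0.1, 1)
  }
  stopifnot(is.numeric(factor), factor > 0)
  if (kind == "remove_link") {
    stopifnot(length(target) == 2L)
  } else {
    stopifnot(length(target) == 1L)
  }
  structure(list(kind = kind, target = as.character(target),
                 factor = factor),
            class = "perturbation")
}

#' Apply a perturbation to a circuit and its parameter ranges
#'
#' The perturbation acts on the pre-estimated ranges, and threshold
#' ranges are deliberately not re-estimated: the perturbed ensemble is
#' the same ensemble of models under treatment, so (for knockout and
#' over/under-expression, which keep the range layout) model `m` run with
#' the same seed shares every untouched parameter draw with its
#' unperturbed counterpart — a paired design.
#'
#' * knockout: the gene's production range becomes `[0, 0]`.
#' * overexpress / knockdown: production range scaled by `factor`.
#' * remove_link: the edge is deleted from the topology and its three
#'   parameters (threshold, Hill coefficient, fold change) are dropped.
#'
#' @param topology A [circuit_topology()].
#' @param ranges Matching `racipe_ranges` from [build_parameter_ranges()].
#' @param spec A [perturbation()] (or a list of them, composed
#'   left-to-right).
#' @return List with elements `topology` and `ranges`, perturbed.
#' @examples
#' topo <- topo_cts("I", 2)
#' set.seed(1)
#' rng <- build_parameter_ranges(topo, mc_samples = 1000)
#' apply_perturbation(topo, rng, perturbation("knockout", "A1"))$ranges
#' @export
apply_perturbation <- function(topology, ranges, spec) {
  stopifnot(inherits(topology, "circuit_topology"),
            identical(ranges$parameter, param_names(topology)))
  if (!inherits(spec, "perturbation")) {
    for (s in spec) {
      out <- apply_perturbation(topology, ranges, s)
      topology <- out$topology
      ranges <- out$ranges
    }
    return(list(topology = topology, ranges = ranges))
  }

  if (spec$kind %in% c("knockout", "overexpress", "knockdown")) {
    gene <- spec$target
    if (!gene %in% topology$genes) stop("unknown gene: ", gene)
    row <- match(paste0("Prod_of_", gene), ranges$parameter)
    if (spec$kind == "knockout") {
      ranges$min[row] <- 0
      ranges$max[row] <- 0
    } else {
      ranges$min[row] <- ranges$min[row] * spec$factor
      ranges$max[row] <- ranges$max[row] * spec$factor
    }
  } else {  # remove_link
    hit <- which(topology$edges$source == spec$target[1] &
                   topology$edges$target == spec$target[2])
    if (!length(hit)) {
      stop("unknown edge: ", spec$target[1], " -> ", spec$target[2])
    }
    ename <- paste0(spec$target[1], "To", spec$target[2])
    drop <- ranges$parameter %in% paste0(c("Trd_of_", "Num_of_", "Fld_of_"),
                                         ename)
    ranges <- ranges[!drop, ]
    edges <- topology$edges[-hit, ]
    if (nrow(edges) == 0L) stop("cannot remove the last edge of a circuit")
    topo2 <- circuit_topology(edges)
    # keep the original gene ordering for genes that remain
    topo2$genes <- intersect(topology$genes, topo2$genes)
    # dropping an edge may strand a gene entirely; its parameters go too
    gone <- setdiff(topology$genes, topo2$genes)
    if (length(gone)) {
      ranges <- ranges[!ranges$parameter %in%
                         c(paste0("Prod_of_", gone), paste0("Deg_of_", gone)), ]
    }
    topology <- topo2
  }
  stopifnot(identical(ranges$parameter, param_names(topology)))
  list(topology = topology, ranges = ranges)
}
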