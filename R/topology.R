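#' Circuit topologies
#'
#' A circuit topology is the only required input of the random circuit
#' perturbation workflow: a set of genes (transcription factors) joined by
#' typed directed regulatory links, where type 1 is transcriptional
#' activation and type 2 is transcriptional inhibition.  The gene list is
#' derived automatically from the edges, in first-appearance order.
#'
#' @param edges A data frame (or tibble) with columns `source`, `target`
#'   and `type` (1 = activation, 2 = inhibition).
#' @return An object of class `circuit_topology`: a list with elements
#'   `genes` (character vector, first-appearance order) and `edges`
#'   (a tibble with columns `source`, `target`, `type`).
#' @examples
#' circuit_topology(tibble::tibble(
#'   source = c("A", "B"), target = c("B", "A"), type = c(2L, 2L)
#' ))
#' @export
circuit_topology <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target", "type") %in% names(edges)))
  edges <- dplyr::mutate(
    edges,
    source = as.character(.data$source),
    target = as.character(.data$target),
    type   = as.integer(.data$type)
  )
  if (nrow(edges) == 0L) {
    stop("empty circuit: a topology needs at least one regulatory link")
  }
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
    stop("gene names must be non-empty")
  }
  bad <- which(!edges$type %in% c(1L, 2L))
  if (length(bad)) {
    stop("unknown interaction type ", edges$type[bad[1]],
         " (edge ", bad[1], "); must be 1 (activation) or 2 (inhibition)")
  }
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate edge: ", d)
  }
  # first-appearance order over the interleaved source/target columns
  genes <- unique(as.vector(t(cbind(edges$source, edges$target))))
  structure(list(genes = genes, edges = edges), class = "circuit_topology")
}

#' Parse a topology file
#'
#' Reads the whitespace-delimited `.topo` format: one regulatory link per
#' line as `Source Target Type`, with an optional header line
#' `Source Target Type` (case-insensitive) that is skipped.  Any run of
#' spaces or tabs delimits fields; blank lines are ignored.
#'
#' @param text Character scalar holding file content, or a character vector
#'   of lines.
#' @return A [circuit_topology()].
#' @examples
#' parse_topo("A B 2\nB A 2")
#' @export
parse_topo <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) &&
      tolower(gsub("[ \t]+", " ", lines[1])) == "source target type") {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (!length(lines)) stop("empty circuit: topology file has no edges")
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    i <- which(nf != 3L)[1]
    stop("malformed topology line ", lineno[i],
         ": expected 3 whitespace-delimited fields, got ", nf[i])
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  type <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(type)) {
    i <- which(is.na(type))[1]
    stop("malformed topology line ", lineno[i],
         ": interaction type '", m[i, 3], "' is not an integer")
  }
  circuit_topology(tibble::tibble(source = m[, 1], target = m[, 2], type = type))
}

#' Read / write topology files
#'
#' @param path Path to a `.topo` file.
#' @return `read_topo()` returns a [circuit_topology()]; `write_topo()`
#'   returns `path` invisibly.
#' @export
read_topo <- function(path) {
  parse_topo(readLines(path, warn = FALSE))
}

#' @rdname read_topo
#' @param topology A [circuit_topology()].
#' @export
write_topo <- function(topology, path) {
  stopifnot(inherits(topology, "circuit_topology"))
  lines <- c("Source Target Type",
             sprintf("%s %s %d", topology$edges$source,
                     topology$edges$target, topology$edges$type))
  writeLines(lines, path)
  invisible(path)
}

#' Coupled toggle-switch circuit generators
#'
#' Builds chains of `n_motifs` toggle-switch motifs: genes `A1..An` and
#' `B1..Bn` with mutual inhibitions `Ai -| Bi`, `Bi -| Ai`.  Variant `"I"`
#' couples consecutive motifs with unidirectional activations
#' `Ai -> Ai+1` and `Bi -> Bi+1`; variant `"II"` uses mutual activations
#' in both directions along each side.  These circuits model chains of
#' coupled binary cell-fate decisions.
#'
#' @param variant `"I"` or `"II"`.
#' @param n_motifs Number of toggle-switch motifs (>= 1).
#' @return A [circuit_topology()] with `2 * n_motifs` genes.
#' @examples
#' topo_cts("I", 5)   # 10 genes, 18 edges
#' @export
topo_cts <- function(variant = c("I", "II"), n_motifs) {
  variant <- match.arg(variant)
  if (!is.numeric(n_motifs) || n_motifs < 1 || n_motifs != round(n_motifs)) {
    stop("n_motifs must be a positive integer")
  }
  n <- as.integer(n_motifs)
  a <- paste0("A", seq_len(n))
  b <- paste0("B", seq_len(n))
  edges <- tibble::tibble(
    source = c(rbind(a, b)),
    target = c(rbind(b, a)),
    type   = 2L
  )
  if (n > 1L) {
    fwd <- tibble::tibble(
      source = c(a[-n], b[-n]),
      target = c(a[-1], b[-1]),
      type   = 1L
    )
    edges <- dplyr::bind_rows(edges, fwd)
    if (variant == "II") {
      back <- tibble::tibble(
        source = c(a[-1], b[-1]),
        target = c(a[-n], b[-n]),
        type   = 1L
      )
      edges <- dplyr::bind_rows(edges, back)
    }
  }
  circuit_topology(edges)
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat("<circuit_topology> ", length(x$genes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  acts <- sum(x$edges$type == 1L)
  cat("edges: ", acts, " activation, ", nrow(x$edges) - acts,
      " inhibition\n", sep = "")
  invisible(x)
}

#' @export
format.circuit_topology <- function(x, ...) {
  paste0("circuit_topology(", length(x$genes), " genes, ",
         nrow(x$edges), " edges)")
}

#' @importFrom generics tidy
#' @export
tidy.circuit_topology <- function(x, ...) {
  x$edges
}
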