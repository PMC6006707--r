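#' Plot the distribution of stable-state counts
#'
#' @param x A `racipe_ensemble`, an integer vector of per-model counts,
#'   or a tibble from [state_count_distribution()].
#' @param max_count Optional common support upper end.
#' @return A ggplot bar chart of the probability of each state count.
#' @export
plot_state_counts <- function(x, max_count = NULL) {
  d <- if (is.data.frame(x) && all(c("n_states", "prob") %in% names(x))) x
       else state_count_distribution(x, max_count)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_states),
                                  y = .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "stable states per model", y = "probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.racipe_pca <- function(object, bins = 60, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(fill = "states") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_state_counts 2-D principal-component density map of
#'   an ensemble's pooled normalized states.
#' @param object,... `autoplot` arguments (an ensemble or fitted PCA).
#' @export
autoplot.racipe_ensemble <- function(object, ...) {
  z <- normalize_expressions(expression_matrix(object))
  autoplot(racipe_pca(z), ...)
}

#' Expression heatmap of clustered stable states
#'
#' Rows (states) are ordered by the clustering dendrogram; columns are
#' genes.  The classic ensemble overview: blocks of rows with a shared
#' expression pattern are the circuit's robust gene states.
#'
#' @param z Normalized expression matrix.
#' @param clusters Optional `racipe_clusters` for row ordering (computed
#'   if missing).
#' @return A ggplot tile heatmap.
#' @export
plot_expression_heatmap <- function(z, clusters = NULL) {
  z <- as.matrix(z)
  if (is.null(clusters)) clusters <- hierarchical_clusters(z)
  ord <- clusters$tree$order
  d <- tibble::tibble(
    state = rep(seq_len(nrow(z)), ncol(z)),
    row = rep(match(seq_len(nrow(z)), ord), ncol(z)),
    gene = rep(colnames(z), each = nrow(z)),
    value = as.vector(z)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black",
                                  high = "yellow") +
    ggplot2::labs(x = NULL, y = "stable state", fill = "z(log2 level)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
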