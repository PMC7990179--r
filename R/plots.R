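#' Bar chart of temporal class counts
#'
#' @param class_counts Tibble from [tabulate_classes()].
#' @param drop_empty Hide zero-count classes (default TRUE).
#' @return A ggplot object.
#' @export
plot_class_counts <- function(class_counts, drop_empty = TRUE) {
  d <- if (drop_empty) class_counts |> filter(.data$n > 0) else class_counts
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$class, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Temporal trajectory classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Stacked bar chart of the TSS/distal binding partition
#'
#' @param partition Tibble from [partition_tss_distal()] (or several,
#'   bound with a `mark` column).
#' @return A ggplot object.
#' @export
plot_tss_partition <- function(partition) {
  if (!"mark" %in% names(partition)) partition$mark <- "mark"
  ggplot2::ggplot(partition,
                  ggplot2::aes(x = .data$mark, y = .data$pct,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of universe",
                  title = "TSS vs distal binding partition") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a cell embedding coloured by cluster
#'
#' @param embedding Cells x dims matrix (e.g. from [pca_embed()]).
#' @param clusters Tibble `barcode`, `cluster`.
#' @param dims Which two dimensions to draw.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, clusters, dims = c(1L, 2L)) {
  d <- tibble(
    barcode = rownames(embedding),
    x = embedding[, dims[1]],
    y = embedding[, dims[2]]
  ) |>
    left_join(clusters, by = "barcode")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::labs(x = paste0("PC", dims[1]), y = paste0("PC", dims[2]),
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a k-means object draws the first two embedding
#' dimensions of its cluster centres with sizes; on an integration report
#' it draws the temporal class-count bar chart.
#'
#' @param object A `cr_kmeans` or `integration_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cr_kmeans <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$dim1, .data$dim2, size = .data$size,
                                  colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = sprintf("k-means centres (k = %d)", object$k),
                  x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cr_kmeans
#' @export
autoplot.integration_report <- function(object, ...) {
  plot_class_counts(object$class_counts)
}
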