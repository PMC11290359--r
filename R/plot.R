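#' Plot embeddings side by side
#'
#' One panel per sample, cells colored by type. Panels share coordinates so
#' aligned embeddings are visually comparable.
#'
#' @param embeddings An embedding tibble (possibly several samples and/or
#'   provenances).
#' @param color Column to color by (default `cell_type`).
#' @return A ggplot object.
#' @export
plot_embeddings <- function(embeddings, color = "cell_type") {
  p <- ggplot2::ggplot(embeddings,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data[[color]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    ggplot2::guides(color = ggplot2::guide_legend(
      override.aes = list(size = 2, alpha = 1)))
  if (length(unique(embeddings$provenance %||% "x")) > 1) {
    p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$provenance),
      cols = ggplot2::vars(.data$sample_id))
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$sample_id))
  }
}

#' @rdname plot_embeddings
#' @param object An [sne_align()] result.
#' @param ... Unused.
#' @export
autoplot.sne_alignment <- function(object, ...) {
  emb <- object$embeddings
  if (!is.null(object$independent)) {
    emb <- dplyr::bind_rows(object$independent, emb)
  }
  plot_embeddings(emb) +
    ggplot2::geom_point(
      data = object$centers,
      ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, shape = 4, size = 2, stroke = 1
    )
}
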