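#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a pairwise signature similarity matrix
#'
#' Signatures are arranged in average-linkage cluster-map order, so blocks of
#' mutually similar signatures appear along the diagonal.
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  ord <- build_cluster_map(object)$leaf_order
  nm <- object$names[ord]
  df <- tibble::as_tibble(as.table(object$sim[ord, ord]), .name_repair = "minimal") |>
    stats::setNames(c("sig_a", "sig_b", "similarity")) |>
    dplyr::mutate(sig_a = factor(.data$sig_a, levels = nm),
                  sig_b = factor(.data$sig_b, levels = nm))
  ggplot2::ggplot(df, ggplot2::aes(.data$sig_a, .data$sig_b, fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' SBS-96 profile plot of a signature matrix
#'
#' The field's standard bar layout: one panel per signature, 96 bars grouped
#' by substitution class.
#'
#' @param object A `signature_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_matrix <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(context = factor(.data$context, levels = sbs96_contexts()))
  ggplot2::ggplot(df, ggplot2::aes(.data$context, .data$probability,
                                   fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~signature, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Explained-variance curve plot
#'
#' @param object An `ev_curve` from [explained_variance_curve()].
#' @param threshold Reference line (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ev_curve <- function(object, threshold = 0.95, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$explained_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "number of archetypes", y = "explained variance") +
    ggplot2::theme_minimal()
}

#' Alpha-coefficient heatmap of an archetype model
#'
#' Signatures in cluster order on the y axis, archetypes on the x axis;
#' coefficients below `display_threshold` are blank (they still drive the
#' clustering).
#'
#' @param object An `archetype_model`.
#' @param display_threshold Mask level for small coefficients (default 0.2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.archetype_model <- function(object, display_threshold = 0.2, ...) {
  grouping <- alpha_grouping(object, display_threshold = display_threshold)
  disp <- grouping$display
  df <- tibble::as_tibble(as.table(disp), .name_repair = "minimal") |>
    stats::setNames(c("signature", "archetype", "alpha")) |>
    dplyr::mutate(signature = factor(.data$signature, levels = rev(rownames(disp))))
  ggplot2::ggplot(df, ggplot2::aes(.data$archetype, .data$signature, fill = .data$alpha)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "alpha") +
    ggplot2::theme_minimal()
}

#' Flatness distribution plot
#'
#' @param sig A [signature_matrix()].
#' @return A ggplot density of per-signature flatness.
#' @export
plot_flatness <- function(sig) {
  df <- signature_flatness(sig)
  ggplot2::ggplot(df, ggplot2::aes(.data$flatness)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "flatness", y = "density") +
    ggplot2::theme_minimal()
}
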