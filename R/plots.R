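# ggplot2 presentation of heatmaps, query results, and evaluation reports.

#' Plot a 5x5 heatmap
#'
#' Prediction heatmaps are faceted by class; feature heatmaps show the single
#' feature grid. Imputed tiles are outlined.
#'
#' @param object An `hp_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hp_heatmap <- function(object, ...) {
  tiles <- object$tiles
  if (object$kind == "prediction") {
    long <- tidyr::pivot_longer(tiles, dplyr::all_of(object$classes),
                                names_to = "class", values_to = "value")
  } else {
    long <- dplyr::mutate(tiles,
                          class = paste0("feature_", object$feature_idx))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                                     fill = .data$value)) +
    ggplot2::geom_tile(ggplot2::aes(color = .data$imputed), linewidth = 0.6) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "grey30", `FALSE` = NA),
                                guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activation") +
    ggplot2::theme_minimal()
}

#' Plot a query result
#'
#' Similarity of the top-ranked corpus records.
#'
#' @param object An `hp_query_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hp_query_result <- function(object, ...) {
  r <- dplyr::mutate(object$ranked, rank = dplyr::row_number())
  ggplot2::ggplot(r, ggplot2::aes(x = .data$rank,
                                  y = .data$similarity_normalized)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = r$rank, labels = r$id) +
    ggplot2::labs(x = NULL, y = "normalized similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an evaluation report
#'
#' LOPO reports show the precision@k curve (per group in grey, overall in
#' color); k-fold reports show per-replicate AUROC.
#'
#' @param object An `hp_eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hp_eval_report <- function(object, ...) {
  if (object$protocol == "lopo") {
    p <- ggplot2::ggplot(object$precision_at_k,
                         ggplot2::aes(x = .data$k, y = .data$precision))
    if (!is.null(object$per_group)) {
      p <- p + ggplot2::geom_line(data = object$per_group,
                                  ggplot2::aes(group = .data$group),
                                  color = "grey70")
    }
    p + ggplot2::geom_line(color = "firebrick", linewidth = 1) +
      ggplot2::geom_point(color = "firebrick") +
      ggplot2::scale_x_continuous(breaks = unique(object$precision_at_k$k)) +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "k", y = "precision@k", title = object$task) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$per_replicate,
                    ggplot2::aes(x = factor(.data$replicate), y = .data$auroc)) +
      ggplot2::geom_point(size = 2, color = "steelblue") +
      ggplot2::geom_hline(yintercept = object$overall, linetype = 2) +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "replicate", y = "weighted AUROC",
                    title = object$task) +
      ggplot2::theme_minimal()
  }
}

#' Plot permutation importances
#'
#' @param importance Tibble from [permutation_importance()].
#' @param top_n Show the `top_n` most important features.
#' @return A ggplot.
#' @export
plot_importance <- function(importance, top_n = 20L) {
  d <- head(dplyr::arrange(importance, dplyr::desc(.data$importance)), top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$feature,
                                                     .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$importance - .data$sd,
                                         xmax = .data$importance + .data$sd),
                            height = 0.3) +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL) +
    ggplot2::theme_minimal()
}
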