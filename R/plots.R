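# ggplot2 visualisations for the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tile probability heatmap
#'
#' Retained tiles are filled by cancer probability; excluded
#' (adipocyte-dominated) tiles are grey.
#'
#' @param object a `tile_prob_map`.
#' @param ... unused.
#' @method autoplot tile_prob_map
#' @export
autoplot.tile_prob_map <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$prob), colour = "white") +
    ggplot2::scale_fill_gradient(low = "black", high = "red",
                                 limits = c(0, 1), na.value = "grey70") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(object$slide_id, " (", object$label, ")"),
                  fill = "P(cancer)", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a ROC curve
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s-level ROC, AUC = %.3f",
                                  object$level, object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a class activation map
#'
#' @param object an `activation_map`.
#' @param ... unused.
#' @method autoplot activation_map
#' @export
autoplot.activation_map <- function(object, ...) {
  m <- object$map
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "activation", x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot an ablation report
#'
#' @param object an `ablation_report`.
#' @param ... unused.
#' @method autoplot ablation_report
#' @export
autoplot.ablation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("tile_auc", "slide_auc"),
                              names_to = "level", values_to = "auc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mode, y = .data$auc,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "training augmentation", y = "AUC on degraded test set",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
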