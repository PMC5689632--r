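#' ROC curve of a cross-validation result
#'
#' @param object An `mda_loocv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mda_loocv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("LOOCV ROC (AUC = %.4f, %d folds)",
                                  object$auc, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Score heatmap of a fitted scorer
#'
#' Tile heatmap of the prediction matrix, known associations outlined.
#'
#' @param object An `mda_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mda_fit <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mirna, y = .data$disease,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(tab, .data$known == 1L),
                       fill = NA, colour = "black", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Convenience wrapper plotting a ROC tibble
#'
#' @param roc Tibble with `fpr` and `tpr` columns.
#' @return A ggplot.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
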