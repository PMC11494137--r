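#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `idp_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot idp_roc
#' @export
autoplot.idp_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)",
      y = "True positive rate (Sn)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' One point per fold for each metric, with the pooled value as a crossbar.
#'
#' @param object An `idp_cv` from [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot idp_cv
#' @export
autoplot.idp_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$per_fold, "fold", "ACC", "MCC", "Sn", "Sp", "AucRoc", "F1"),
    cols = -"fold", names_to = "metric", values_to = "value"
  )
  pooled <- tidyr::pivot_longer(
    dplyr::select(object$pooled, "ACC", "MCC", "Sn", "Sp", "AucRoc", "F1"),
    cols = dplyr::everything(), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1.6) +
    ggplot2::geom_point(
      data = pooled, colour = "#b2182b", shape = 95, size = 9
    ) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%d-fold cross-validation, %s", object$k, object$kind),
      subtitle = "points: folds; red bar: pooled over held-out predictions"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a decision-boundary map
#'
#' Probability field over the first two principal components, red for the
#' disordered (positive) subspace and blue for the ordered one, with the
#' projected labeled points overlaid.
#'
#' @param object An `idp_boundary` from [decision_boundary_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot idp_boundary
#' @export
autoplot.idp_boundary <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0.5,
      limits = c(0, 1), name = "P(disordered)"
    ) +
    ggplot2::geom_contour(
      ggplot2::aes(z = .data$prob),
      breaks = 0.5, colour = "grey20", linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = object$points,
      ggplot2::aes(shape = factor(.data$label)),
      size = 1.4, alpha = 0.7
    ) +
    ggplot2::scale_shape_manual(
      values = c(`0` = 1, `1` = 17), name = "class",
      labels = c(`0` = "ordered", `1` = "disordered")
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2]),
      title = "Decision boundary over the first two principal components"
    ) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Train and validation loss per epoch for a fitted classifier.
#'
#' @param model A trained `idp_model`.
#' @return A ggplot.
#' @export
plot_training_history <- function(model) {
  stopifnot(inherits(model, "idp_model"), isTRUE(model$trained))
  long <- tidyr::pivot_longer(model$history,
    cols = c("train_loss", "val_loss"),
    names_to = "split", values_to = "loss"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = model$best_epoch, linetype = "dotted") +
    ggplot2::labs(
      x = "epoch", y = "binary cross-entropy",
      title = sprintf("%s training history (best epoch %d)", model$config$kind, model$best_epoch)
    ) +
    ggplot2::theme_minimal()
}
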