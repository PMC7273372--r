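#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `enzid_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enzid_roc
#' @export
autoplot.enzid_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv", linewidth = 0.8,
                       colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an incremental-selection accuracy curve
#'
#' Cross-validated accuracy as a function of the number of k-spaced pairs
#' added to the AAC base; the chosen subset size is marked.
#'
#' @param object An `enzid_selection` from [select_incremental()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enzid_selection
#' @export
autoplot.enzid_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$m, y = .data$acc)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_vline(xintercept = object$best_m, linetype = "dotted") +
    ggplot2::labs(x = sprintf("CKSAAP(k=%d) pairs added to AAC", object$k),
                  y = "Pooled CV accuracy (%)",
                  title = sprintf("Incremental selection (best m = %d)",
                                  object$best_m)) +
    ggplot2::theme_minimal()
}

#' Plot a grid-search accuracy surface
#'
#' Pooled cross-validated accuracy over the (log2 c, log2 gamma) grid,
#' with the winning point marked.
#'
#' @param object An `enzid_grid` from [grid_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enzid_grid
#' @export
autoplot.enzid_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$log2c, y = .data$log2gamma,
                               fill = .data$acc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "ACC (%)") +
    ggplot2::labs(x = expression(log[2] ~ c),
                  y = expression(log[2] ~ gamma),
                  title = "Grid-search accuracy surface") +
    ggplot2::theme_minimal()
}

#' Plot top-ranked features of a selection
#'
#' F statistics of the top-ranked k-spaced pairs, descending.
#'
#' @param selection An `enzid_selection`.
#' @param top_n How many pairs to show.
#' @return A ggplot.
#' @export
plot_fscores <- function(selection, top_n = 30) {
  d <- utils::head(selection$ranking, top_n)
  d$descriptor <- factor(d$descriptor, levels = rev(d$descriptor))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$F, y = .data$descriptor)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "ANOVA F statistic", y = NULL,
                  title = sprintf("Top %d CKSAAP(k=%d) pairs", nrow(d),
                                  selection$k)) +
    ggplot2::theme_minimal()
}
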