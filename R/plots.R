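#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an experiment result table
#'
#' Boxplots of the lin-minus-model accuracy difference (noise-free runs)
#' or of accuracy over the noise level (noise runs), faceted by concept
#' class and coloured by regularization.
#'
#' @param object a tibble from [noise_free_experiment()] or
#'   [noise_experiment()].
#' @param value column to plot; default `accuracy_diff_vs_lin` for
#'   noise-free results and `accuracy` for noise results.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.consvm_experiment <- function(object, value = NULL, ...) {
  is_noise <- "p" %in% names(object)
  if (is.null(value)) value <- if (is_noise) "accuracy" else "accuracy_diff_vs_lin"
  xvar <- if (is_noise) "p" else "d"
  df <- dplyr::filter(object, .data$concept_class != "lin" | is_noise)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data[[xvar]]),
    y = .data[[value]],
    fill = .data$regularization
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::facet_wrap(~concept_class) +
    ggplot2::labs(
      x = if (is_noise) "noise level p" else "centroid distance d",
      y = value
    ) +
    ggplot2::theme_minimal()
}

#' Plot the weight profile of a fitted constrained SVM
#'
#' @param fit an [svm_train()] fit.
#' @return a ggplot object (bar chart of weights; the threshold is shown
#'   in the subtitle).
#' @export
plot_weights <- function(fit) {
  td <- tidy(fit)
  td <- td[td$term != "(threshold)", ]
  td$term <- factor(td$term, levels = td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("%s SVM, class %s", fit$regularization, fit$concept_class),
      subtitle = sprintf("t = %.4g, sparsity %d / %d",
                         fit$model$t, sparsity(fit$model$w), fit$n),
      x = NULL, y = "weight"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
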