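#' Plot the ROC curve of a panel evaluation
#'
#' @param object a [evaluate_panel()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.resistance_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False resistance rate", y = "True resistance rate",
      title = sprintf("ROC (AUC = %.3f)", object$metrics$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot accuracy against resistant-subset size
#'
#' Mean and standard deviation of prediction accuracy as the panel is
#' rebalanced by subsampling the resistant class.
#'
#' @param object an [imbalance_resample()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.imbalance_resample <- function(object, ...) {
  df <- object$summary %>%
    mutate(sd_accuracy = ifelse(is.na(.data$sd_accuracy), 0,
                                .data$sd_accuracy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_accuracy - .data$sd_accuracy, 0),
      ymax = pmin(.data$mean_accuracy + .data$sd_accuracy, 1)
    ), fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Resistant variants retained (k)",
                  y = "Accuracy (mean ± SD)",
                  title = "Sensitivity to class imbalance") +
    ggplot2::theme_minimal()
}

#' Plot the metric distributions of a grid evaluation
#'
#' Boxplots of accuracy, enrichment factor and AUC across grid cells,
#' grouped by the compared factor.
#'
#' @param object an [evaluate_grid()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grid_eval <- function(object, ...) {
  long <- object$metrics %>%
    tidyr::pivot_longer(c("accuracy", "ef", "auc"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[object$compare_var]],
                                     y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of panel binding scores
#'
#' Variants ordered from weak to strong binding, coloured by their
#' experimental label, with the wild-type score marked.
#'
#' @param scores tibble with `variant_id` and `dg`.
#' @param labels optional tibble with `variant_id` and `label`.
#' @return a ggplot.
#' @export
plot_panel_scores <- function(scores, labels = NULL) {
  df <- if (!is.null(labels)) {
    rank_panel(scores, labels)
  } else if ("label" %in% names(scores)) {
    rank_panel(scores)
  } else {
    scores %>% arrange(dplyr::desc(.data$dg)) %>%
      mutate(rank = row_number(), label = "unlabelled")
  }
  wt_dg <- df$dg[df$variant_id == "WT"]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variant_id, -.data$rank),
    y = .data$dg, fill = .data$label
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Binding free energy (kcal/mol)",
                  fill = "Label") +
    ggplot2::theme_minimal()
  if (length(wt_dg) == 1) {
    p <- p + ggplot2::geom_hline(yintercept = wt_dg, linetype = "dotted")
  }
  p
}
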