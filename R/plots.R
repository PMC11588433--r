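#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_abline
#'   geom_boxplot geom_tile labs theme_minimal scale_fill_gradient2 facet_wrap
NULL

#' Plot a soft-threshold scan
#'
#' Scale-free fit (signed R-squared) against candidate powers, with the
#' chosen power highlighted and the acceptance threshold drawn.
#'
#' @param object A `soft_threshold_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot soft_threshold_scan
#' @export
autoplot.soft_threshold_scan <- function(object, ...) {
  df <- object$scan
  ggplot(df, aes(x = .data$power, y = .data$fit_r2)) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = .data$power == object$chosen_power), size = 2) +
    geom_hline(yintercept = object$r2_threshold, linetype = "dashed") +
    labs(x = "soft-threshold power", y = "scale-free fit (signed R²)",
         colour = "chosen") +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_analysis
#' @export
autoplot.roc_analysis <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Plot a cross-validation benchmark
#'
#' Per-fold held-out AUC by model across repetitions.
#'
#' @param object A `cv_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_benchmark
#' @export
autoplot.cv_benchmark <- function(object, ...) {
  ggplot(object$grid, aes(x = stats::reorder(.data$model, .data$auc, FUN = mean),
                          y = .data$auc)) +
    geom_boxplot() +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    labs(x = NULL, y = "held-out AUC") +
    theme_minimal()
}

#' Heatmap of one sample's gene-immune portrait
#'
#' @param stack A `portrait_stack`.
#' @param sample Sample id (or index) to draw.
#' @return A ggplot.
#' @export
plot_portrait <- function(stack, sample = 1) {
  m <- stack[sample, , ]
  df <- as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "population", values_to = "value")
  ggplot(df, aes(x = .data$population, y = .data$gene, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(x = NULL, y = NULL, fill = "ratio") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
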