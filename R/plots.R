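#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   labs theme_minimal geom_histogram facet_wrap geom_smooth
NULL

#' Plot a ROC curve
#'
#' @param object A `ptb_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ptb_roc
#' @export
autoplot.ptb_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#b2182b") +
    geom_point(size = 0.8, colour = "#b2182b") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot score vs experimental free energy with the fitted trend
#'
#' @param object A `ptb_benchmark` containing a correlation block.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ptb_benchmark
#' @export
autoplot.ptb_benchmark <- function(object, ...) {
  if (!is.null(object$roc) && is.null(object$correlation)) {
    return(autoplot(object$roc))
  }
  stopifnot(!is.null(object$correlation))
  ggplot(object$per_peptide, aes(x = .data$delta_g, y = .data$score)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "grey40", linewidth = 0.5) +
    labs(x = expression(Delta * G ~ "(kcal/mol)"),
         y = "Pair potential score",
         title = sprintf("r = %.2f (n = %d, p = %.2g)",
                         object$correlation$r, object$correlation$n,
                         object$correlation$p_value)) +
    theme_minimal()
}

#' Score distributions by binder class
#'
#' Histograms of pair-potential scores for binders vs non-binders, the
#' visual counterpart of the per-class score ranges in the benchmark
#' report.
#'
#' @param scores Tibble with `score` and `label` columns.
#' @param bins Histogram bins (default 30).
#' @return A ggplot.
#' @export
plot_score_distributions <- function(scores, bins = 30) {
  check_labels(scores)
  ggplot(scores, aes(x = .data$score)) +
    geom_histogram(bins = bins, fill = "#2166ac", colour = "white") +
    facet_wrap(~label, ncol = 1) +
    labs(x = "Pair potential score (lower = more favorable)",
         y = "Peptides") +
    theme_minimal()
}
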