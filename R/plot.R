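#' @rdname compare_auc
#' @param object A `model_comparison`.
#' @export
autoplot.model_comparison <- function(object, ...) {
  pts <- dplyr::bind_rows(
    dplyr::mutate(roc_points(object$scores_a, object$labels),
                  model = sprintf("%s (AUC %.3f)", object$name_a, object$auc_a)),
    dplyr::mutate(roc_points(object$scores_b, object$labels),
                  model = sprintf("%s (AUC %.3f)", object$name_b, object$auc_b)))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  subtitle = sprintf("paired p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-condition AUCs with confidence intervals
#'
#' Point-range display of a summary table (one row per condition or model
#' variant) in the style of an ablation figure.
#'
#' @param summary A tibble with columns `condition`, `auc`, `ci_lower`,
#'   `ci_upper`.
#' @return A ggplot object.
#' @export
plot_condition_auc <- function(summary) {
  stopifnot(all(c("condition", "auc") %in% names(summary)))
  summary$condition <- factor(summary$condition,
                              levels = summary$condition[order(summary$auc)])
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$auc, y = .data$condition))
  if (all(c("ci_lower", "ci_upper") %in% names(summary))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2, colour = "grey40")
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "AUC (out-of-fold)", y = NULL) +
    ggplot2::theme_minimal()
}
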