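#' Plot an ROC curve
#'
#' @param object An `adc_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adc_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s (positive: %s)", object$parameter,
                      object$positive_class),
      subtitle = sprintf("AUC = %.4f [%.4f-%.4f], p = %.4g",
                         object$auc, object$ci_low, object$ci_high,
                         object$p_value)) +
    ggplot2::theme_minimal()
}

#' Boxplots of histogram parameters by group
#'
#' One panel per parameter, the conventional way significant grade-wise
#' differences are displayed.
#'
#' @param cohort Cohort tibble.
#' @param parameters Parameter columns to show (default all 13).
#' @param grouping `"grade"` or `"mgmt"`.
#' @return A ggplot.
#' @export
plot_parameter_boxplots <- function(cohort, parameters = adc_parameter_names(),
                                    grouping = c("grade", "mgmt")) {
  grouping <- match.arg(grouping)
  cohort <- validate_cohort(cohort)
  col <- if (grouping == "grade") "who_grade" else "mgmt"
  d <- cohort[, c(col, parameters)]
  if (grouping == "mgmt") d <- d[d[[col]] %in% c("methylated", "unmethylated"), ]
  long <- tidyr::pivot_longer(d, dplyr::all_of(parameters),
                              names_to = "parameter", values_to = "value")
  long$parameter <- factor(long$parameter, levels = parameters)
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[col]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Value (ADC parameters in 1e-5 mm²/s)") +
    ggplot2::theme_minimal()
}
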