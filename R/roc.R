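#' ROC analysis of a histogram parameter
#'
#' Builds the empirical ROC curve of one parameter for discriminating a
#' positive class (default WHO grade IV) and computes the AUC through the
#' Mann-Whitney identity: AUC = U / (n_pos * n_neg), counting ties as 1/2.
#' The polarity is oriented so that AUC >= 0.5 and recorded
#' (`higher_positive` when larger values indicate the positive class,
#' `lower_positive` otherwise). The 95% CI uses the Hanley-McNeil standard
#' error by default (`ci_method = "delong"` for DeLong's covariance-based
#' SE); the p-value tests AUC = 0.5 with a z-statistic on that SE.
#'
#' @inheritParams compare_groups
#' @param parameter Parameter column to evaluate.
#' @param positive_class Level of `class_column` treated as positive
#'   (default `"IV"`).
#' @param class_column Column holding the class labels (default
#'   `"who_grade"`).
#' @param ci_method `"hanley_mcneil"` or `"delong"`.
#' @param conf_level Confidence level for the AUC CI.
#' @return An object of class `adc_roc` with the oriented AUC, CI, p-value,
#'   the Youden-optimal operating point and the ROC curve points; see
#'   [tidy()], [glance()] and [autoplot()].
#' @export
roc_analysis <- function(cohort, parameter, positive_class = "IV",
                         class_column = "who_grade",
                         ci_method = c("hanley_mcneil", "delong"),
                         conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (!all(c(parameter, class_column) %in% names(cohort))) {
    abort(sprintf("Cohort needs columns '%s' and '%s'.",
                  parameter, class_column),
          class = "adchist_validation_error")
  }
  ok <- !is.na(cohort[[parameter]]) & !is.na(cohort[[class_column]])
  x <- cohort[[parameter]][ok]
  pos <- cohort[[class_column]][ok] == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2L || n0 < 2L) {
    abort(sprintf("Need >= 2 members per class (got %d positive, %d negative).",
                  n1, n0),
          class = "adchist_insufficient_group")
  }

  auc_raw <- auc_mann_whitney(x[pos], x[!pos])
  polarity <- if (auc_raw >= 0.5) "higher_positive" else "lower_positive"
  score <- if (polarity == "higher_positive") x else -x
  auc <- max(auc_raw, 1 - auc_raw)

  se <- switch(ci_method,
    hanley_mcneil = hanley_mcneil_se(auc, n1, n0),
    delong = delong_se(score[pos], score[!pos])
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-z, z) * se, 0), 1)
  p <- if (se == 0) as.numeric(auc == 0.5) else
    2 * pnorm(-abs(auc - 0.5) / se)

  curve <- roc_points(score, pos)
  yj <- youden_search(score, pos)
  cutoff <- if (polarity == "higher_positive") yj$threshold else -yj$threshold

  structure(list(
    parameter = parameter, positive_class = positive_class,
    polarity = polarity, n_pos = n1, n_neg = n0,
    auc = auc, ci_low = ci[1], ci_high = ci[2], se = se, p_value = p,
    ci_method = ci_method,
    youden = list(cutoff = cutoff, j = yj$j,
                  sensitivity = yj$sensitivity, specificity = yj$specificity),
    curve = curve
  ), class = "adc_roc")
}

# AUC = P(X_pos > X_neg) + 0.5 P(tie), via midranks: O(n log n)
auc_mann_whitney <- function(xpos, xneg) {
  r <- rank(c(xpos, xneg)) # midranks
  n1 <- length(xpos); n0 <- length(xneg)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

hanley_mcneil_se <- function(auc, n1, n0) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
        (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}

# DeLong's placement-based SE for a single empirical AUC
delong_se <- function(xpos, xneg) {
  n1 <- length(xpos); n0 <- length(xneg)
  v10 <- vapply(xpos, function(a) mean((a > xneg) + 0.5 * (a == xneg)), 0)
  v01 <- vapply(xneg, function(b) mean((xpos > b) + 0.5 * (xpos == b)), 0)
  sqrt(var(v10) / n1 + var(v01) / n0)
}

# empirical ROC points over all distinct thresholds of the oriented score
roc_points <- function(score, pos) {
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[!pos] >= t), 0)
  tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

# maximize J over midpoint candidates (and the +/-Inf endpoints) of the
# oriented score; ties broken toward higher specificity, then higher threshold
youden_search <- function(score, pos) {
  s <- sort(unique(score))
  cand <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  sens <- vapply(cand, function(t) mean(score[pos] >= t), 0)
  spec <- vapply(cand, function(t) mean(score[!pos] < t), 0)
  j <- sens + spec - 1
  # sens/spec are ratios of small integers; compare J with a tolerance so
  # floating-point noise cannot break ties incorrectly
  best <- which(j >= max(j) - 1e-12)
  best <- best[spec[best] >= max(spec[best]) - 1e-12]
  best <- best[which.max(cand[best])]
  list(threshold = cand[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Youden-optimal cut-off of an ROC result
#'
#' @param roc An `adc_roc` from [roc_analysis()].
#' @param report_scale mm^2/s per reported unit, used for `cutoff_canonical`
#'   when the parameter is ADC-valued (reported values are already in report
#'   units).
#' @return A one-row tibble: `parameter`, `polarity`, `cutoff` (report
#'   units), `cutoff_canonical` (mm^2/s), `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc, report_scale = default_report_scale()) {
  stopifnot(inherits(roc, "adc_roc"))
  y <- roc$youden
  adc_valued <- !roc$parameter %in% c("Kurtosis", "Skewness", "Entropy", "ki67")
  tibble(
    parameter = roc$parameter, polarity = roc$polarity,
    cutoff = y$cutoff,
    cutoff_canonical = if (adc_valued) y$cutoff * report_scale else y$cutoff,
    j = y$j, sensitivity = y$sensitivity, specificity = y$specificity
  )
}

#' @export
print.adc_roc <- function(x, ...) {
  cat(sprintf(
    "<adc_roc> %s (positive: %s, %s): AUC = %.4f [%.4f-%.4f], p = %.4g\n",
    x$parameter, x$positive_class, x$polarity,
    x$auc, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  Youden cut-off %.4g: sensitivity %.2f, specificity %.2f\n",
              x$youden$cutoff, x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x An `adc_roc` object.
#' @param ... Unused.
#' @export
tidy.adc_roc <- function(x, ...) x$curve

#' @rdname roc_analysis
#' @export
glance.adc_roc <- function(x, ...) {
  tibble(parameter = x$parameter, positive_class = x$positive_class,
         polarity = x$polarity, n_pos = x$n_pos, n_neg = x$n_neg,
         auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value, ci_method = x$ci_method,
         cutoff = x$youden$cutoff, sensitivity = x$youden$sensitivity,
         specificity = x$youden$specificity)
}
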