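#' Normality-gated correlation with the Ki-67 proliferation index
#'
#' Pearson's correlation is used only when both the parameter and Ki-67 pass
#' the Shapiro-Wilk gate on the pooled cohort; otherwise Spearman's rank
#' correlation (midranks for ties). Two-sided p-values use the
#' t-approximation on r in both cases.
#'
#' @inheritParams compare_groups
#' @param parameter Histogram parameter column to correlate against `ki67`.
#' @return An object of class `adc_correlation`; [tidy()] gives a one-row
#'   tibble with `parameter`, `method`, `r`, `p_value`, `n`.
#' @export
correlate_ki67 <- function(cohort, parameter, alpha = 0.05) {
  if (!all(c(parameter, "ki67") %in% names(cohort))) {
    abort(sprintf("Cohort needs columns '%s' and 'ki67'.", parameter),
          class = "adchist_validation_error")
  }
  ok <- complete.cases(cohort[[parameter]], cohort$ki67)
  x <- cohort[[parameter]][ok]
  y <- cohort$ki67[ok]
  if (length(x) < 4L) {
    abort("Need >= 4 complete (parameter, ki67) pairs.",
          class = "adchist_validation_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Zero variance: correlation undefined.",
          class = "adchist_zero_variance")
  }
  gx <- shapiro_gaussian(x, alpha)$is_gaussian
  gy <- shapiro_gaussian(y, alpha)$is_gaussian
  method <- if (gx && gy) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  structure(list(parameter = parameter, method = method,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), gaussian = c(parameter = gx, ki67 = gy)),
            class = "adc_correlation")
}

#' @export
print.adc_correlation <- function(x, ...) {
  cat(sprintf("<adc_correlation> %s vs Ki-67 (%s): r = %.4f, p = %.4g, n = %d\n",
              x$parameter, x$method, x$r, x$p_value, x$n))
  invisible(x)
}

#' @rdname correlate_ki67
#' @param x An `adc_correlation` object.
#' @param ... Unused.
#' @export
tidy.adc_correlation <- function(x, ...) {
  tibble(parameter = x$parameter, method = x$method, r = x$r,
         p_value = x$p_value, n = x$n)
}
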