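#' Shapiro-Wilk normality gate
#'
#' Wraps the Shapiro-Wilk test (Royston's algorithm, as in
#' [stats::shapiro.test()]) into the yes/no gate used to dispatch between
#' parametric and rank-based procedures: a sample is treated as Gaussian iff
#' the test does not reject at level `alpha`.
#'
#' @param values Numeric sample, 3 <= n <= 5000 after dropping NA.
#' @param alpha Gate level (default 0.05).
#' @return A list with `statistic` (W), `p_value` and `is_gaussian`.
#' @export
shapiro_gaussian <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    abort(sprintf("Shapiro-Wilk needs 3 <= n <= 5000 (got %d).", n),
          class = "adchist_validation_error")
  }
  if (length(unique(values)) == 1L) {
    warn("Constant sample: treated as non-Gaussian.",
         class = "adchist_zero_variance")
    return(list(statistic = NA_real_, p_value = 0, is_gaussian = FALSE))
  }
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       is_gaussian = sw$p.value >= alpha)
}

#' Pooled-variance t-test from summary statistics
#'
#' Two-sided unpaired Student's t-test computed from group means, SDs and
#' sizes alone, so published group summaries can be checked without the raw
#' per-patient data.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A tibble with `t`, `df`, `p_value`, `mean_diff`.
#' @export
#' @examples
#' summary_ttest(136.90, 29.88, 11, 137.70, 32.68, 45)
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2 || sd1 < 0 || sd2 < 0) {
    abort("Need n >= 2 and sd >= 0 in both groups.",
          class = "adchist_validation_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean1 - mean2
  if (sp2 == 0) {
    # degenerate: both groups constant
    return(tibble(t = if (diff == 0) 0 else Inf * sign(diff), df = df,
                  p_value = if (diff == 0) 1 else 0, mean_diff = diff))
  }
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- diff / se
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df), mean_diff = diff)
}
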