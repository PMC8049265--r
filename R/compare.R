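#' Normality-gated two-group comparison
#'
#' Compares one histogram parameter (or Ki-67) between two patient groups.
#' Gaussianity is assessed with [shapiro_gaussian()]; if the gate passes, an
#' unpaired Student's t-test (pooled variance, two-sided) is used, otherwise
#' a two-sided Mann-Whitney U test (exact enumeration when both groups have
#' n <= 8 and no ties, else the normal approximation with continuity and tie
#' correction). Group means, SDs and t-based 95% CIs of the mean are always
#' reported regardless of which test ran.
#'
#' @param cohort Tibble with one row per patient (see [read_cohort_csv()]).
#' @param grouping `"grade"` (WHO III vs IV) or `"mgmt"` (methylated vs
#'   unmethylated; `unknown` rows are dropped).
#' @param parameter Column to compare: one of [adc_parameter_names()] or
#'   `"ki67"`.
#' @param alpha Gate level for the Shapiro-Wilk dispatch.
#' @param gate_mode `"per_group"` requires both groups to pass the gate for
#'   the t-test; `"cohort_wide"` gates on the pooled values (the convention
#'   of some clinical analyses, retained for reproducing them).
#' @param t_variant `"student"` (pooled variance) or `"welch"`.
#' @return An object of class `adc_comparison`; use [tidy()] for a one-row
#'   tibble.
#' @export
compare_groups <- function(cohort, grouping = c("grade", "mgmt"), parameter,
                           alpha = 0.05,
                           gate_mode = c("per_group", "cohort_wide"),
                           t_variant = c("student", "welch")) {
  grouping <- match.arg(grouping)
  gate_mode <- match.arg(gate_mode)
  t_variant <- match.arg(t_variant)
  g <- split_groups(cohort, grouping, parameter)
  x <- g$values1; y <- g$values2

  if (length(x) < 3L || length(y) < 3L) {
    abort(sprintf("Group sizes %d/%d too small for '%s' (need >= 3 each).",
                  length(x), length(y), parameter),
          class = "adchist_insufficient_group")
  }

  gauss <- gate_gaussian(x, y, alpha, gate_mode)
  if (gauss$use_parametric) {
    tt <- t.test(x, y, var.equal = (t_variant == "student"))
    test_used <- if (t_variant == "student") "student_t" else "welch_t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = mw_exact_ok(x, y), correct = TRUE)
    )
    test_used <- "mann_whitney_u"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }

  structure(list(
    parameter = parameter,
    grouping = grouping,
    groups = tibble(
      group = c(g$label1, g$label2),
      n = c(length(x), length(y)),
      mean = c(mean(x), mean(y)),
      sd = c(sd(x), sd(y)),
      ci_low = c(mean_ci(x)[1], mean_ci(y)[1]),
      ci_high = c(mean_ci(x)[2], mean_ci(y)[2]),
      gaussian = gauss$flags
    ),
    test_used = test_used,
    gate_mode = gate_mode,
    statistic = statistic,
    p_value = p,
    mean_diff = mean(x) - mean(y)
  ), class = "adc_comparison")
}

gate_gaussian <- function(x, y, alpha, gate_mode) {
  if (gate_mode == "cohort_wide") {
    g <- shapiro_gaussian(c(x, y), alpha)$is_gaussian
    list(use_parametric = g, flags = c(g, g))
  } else {
    gx <- shapiro_gaussian(x, alpha)$is_gaussian
    gy <- shapiro_gaussian(y, alpha)$is_gaussian
    list(use_parametric = gx && gy, flags = c(gx, gy))
  }
}

mw_exact_ok <- function(x, y) {
  length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
}

mean_ci <- function(v, level = 0.95) {
  n <- length(v)
  half <- qt(1 - (1 - level) / 2, n - 1) * sd(v) / sqrt(n)
  mean(v) + c(-half, half)
}

split_groups <- function(cohort, grouping, parameter) {
  if (!parameter %in% names(cohort)) {
    abort(sprintf("Cohort has no column '%s'.", parameter),
          class = "adchist_validation_error")
  }
  if (grouping == "grade") {
    col <- "who_grade"; lab1 <- "III"; lab2 <- "IV"
  } else {
    col <- "mgmt"; lab1 <- "methylated"; lab2 <- "unmethylated"
  }
  if (!col %in% names(cohort)) {
    abort(sprintf("Cohort has no column '%s'.", col),
          class = "adchist_validation_error")
  }
  keep <- !is.na(cohort[[col]]) & !is.na(cohort[[parameter]])
  if (grouping == "mgmt") keep <- keep & cohort[[col]] %in% c(lab1, lab2)
  d <- cohort[keep, ]
  v1 <- d[[parameter]][d[[col]] == lab1]
  v2 <- d[[parameter]][d[[col]] == lab2]
  if (length(v1) == 0L || length(v2) == 0L) {
    abort(sprintf("Empty group for '%s' split (%s vs %s).",
                  grouping, lab1, lab2),
          class = "adchist_insufficient_group")
  }
  list(values1 = v1, values2 = v2, label1 = lab1, label2 = lab2)
}

#' @export
print.adc_comparison <- function(x, ...) {
  cat(sprintf("<adc_comparison> %s by %s: %s, p = %.4g\n",
              x$parameter, x$grouping, x$test_used, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `adc_comparison` object.
#' @param ... Unused.
#' @export
tidy.adc_comparison <- function(x, ...) {
  g <- x$groups
  tibble(
    parameter = x$parameter, grouping = x$grouping,
    group1 = g$group[1], n1 = g$n[1], mean1 = g$mean[1], sd1 = g$sd[1],
    ci1_low = g$ci_low[1], ci1_high = g$ci_high[1],
    group2 = g$group[2], n2 = g$n[2], mean2 = g$mean[2], sd2 = g$sd[2],
    ci2_low = g$ci_low[2], ci2_high = g$ci_high[2],
    gaussian1 = g$gaussian[1], gaussian2 = g$gaussian[2],
    test_used = x$test_used, statistic = x$statistic, p_value = x$p_value
  )
}
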