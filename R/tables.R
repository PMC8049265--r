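#' Read a per-patient feature/label cohort CSV
#'
#' Expects the schema written by [write_profiles_csv()] plus the label
#' columns `who_grade` ("III"/"IV" or 3/4), `ki67` (percent, 0-100) and
#' `mgmt` ("methylated"/"unmethylated"/"unknown"). A transcribed per-patient
#' supplementary table with these headers loads directly.
#'
#' @param path CSV path.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  validate_cohort(d)
}

#' Validate a cohort tibble
#'
#' @param cohort Tibble with `patient_id`, the 13 parameter columns and the
#'   label columns.
#' @return The cohort, with labels normalised.
#' @export
validate_cohort <- function(cohort) {
  need <- c("patient_id", adc_parameter_names(), "who_grade")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort(sprintf("Cohort is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "adchist_validation_error")
  }
  if (anyDuplicated(cohort$patient_id)) {
    abort("Duplicate patient_id values.", class = "adchist_validation_error")
  }
  g <- as.character(cohort$who_grade)
  g[g %in% c("3", "III")] <- "III"
  g[g %in% c("4", "IV")] <- "IV"
  bad <- !g %in% c("III", "IV") & !is.na(g)
  if (any(bad)) {
    abort(sprintf("who_grade must be III or IV (got: %s).",
                  paste(unique(g[bad]), collapse = ", ")),
          class = "adchist_validation_error")
  }
  cohort$who_grade <- g
  if (!"ki67" %in% names(cohort)) cohort$ki67 <- NA_real_
  if (any(cohort$ki67 < 0 | cohort$ki67 > 100, na.rm = TRUE)) {
    abort("ki67 must lie in [0, 100].", class = "adchist_validation_error")
  }
  if (!"mgmt" %in% names(cohort)) cohort$mgmt <- "unknown"
  m <- tolower(as.character(cohort$mgmt))
  m[is.na(m) | !m %in% c("methylated", "unmethylated")] <- "unknown"
  cohort$mgmt <- m
  as_tibble(cohort)
}

#' Full cohort statistics stage
#'
#' Runs the descriptive, comparative, correlative and ROC analyses of a
#' profiled cohort:
#' * `table1`: per-parameter mean, SD, min, max over all patients.
#' * `table2`: WHO grade III vs IV comparison of the 13 parameters plus
#'   Ki-67 (normality-gated t / Mann-Whitney dispatch).
#' * `table3`: MGMT methylated vs unmethylated comparison of the 13
#'   parameters (`unknown` dropped).
#' * `table4`: gated Pearson/Spearman correlation of each parameter with
#'   Ki-67.
#' * `roc`: ROC + Youden cut-off for every parameter significant in
#'   `table2` (grade discrimination).
#'
#' Significance is marked at `alpha` with no multiplicity correction by
#' default, mirroring a serial-univariate exploratory analysis;
#' `multiplicity = "holm"` adds Holm-adjusted p-values and bases the
#' significance flags (and ROC parameter selection) on them.
#'
#' @inheritParams compare_groups
#' @param roc_ci_method Passed to [roc_analysis()].
#' @param multiplicity `"none"` or `"holm"`.
#' @return A list of tibbles `table1`, `table2`, `table3`, `table4`, `roc`,
#'   plus `roc_objects` (named list of `adc_roc`) and `config` (the
#'   statistical settings used).
#' @export
build_tables <- function(cohort, alpha = 0.05,
                         gate_mode = c("per_group", "cohort_wide"),
                         t_variant = c("student", "welch"),
                         roc_ci_method = c("hanley_mcneil", "delong"),
                         multiplicity = c("none", "holm")) {
  gate_mode <- match.arg(gate_mode)
  t_variant <- match.arg(t_variant)
  roc_ci_method <- match.arg(roc_ci_method)
  multiplicity <- match.arg(multiplicity)
  cohort <- validate_cohort(cohort)
  params <- adc_parameter_names()

  table1 <- purrr::map(params, function(p) {
    v <- cohort[[p]][!is.na(cohort[[p]])]
    tibble(parameter = p, mean = mean(v), sd = sd(v),
           min = min(v), max = max(v), n = length(v))
  }) |> dplyr::bind_rows()

  run_rows <- function(parameters, grouping) {
    purrr::map(parameters, function(p) {
      tryCatch(
        tidy(compare_groups(cohort, grouping, p, alpha = alpha,
                            gate_mode = gate_mode, t_variant = t_variant)),
        error = function(e) {
          message(sprintf("build_tables: %s comparison of %s failed: %s",
                          grouping, p, conditionMessage(e)))
          NULL
        })
    }) |> dplyr::bind_rows()
  }

  table2 <- run_rows(c(params, "ki67"), "grade")
  table3 <- if (sum(cohort$mgmt == "methylated") > 0 &&
                sum(cohort$mgmt == "unmethylated") > 0) {
    run_rows(params, "mgmt")
  } else {
    tibble()
  }

  table4 <- purrr::map(params, function(p) {
    tryCatch(tidy(correlate_ki67(cohort, p, alpha = alpha)),
             error = function(e) {
               message(sprintf("build_tables: correlation of %s failed: %s",
                               p, conditionMessage(e)))
               NULL
             })
  }) |> dplyr::bind_rows()

  mark <- function(tab) {
    if (nrow(tab) == 0L) return(tab)
    if (multiplicity == "holm") {
      tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "holm")
      tab$significant <- tab$p_adjusted < alpha
    } else {
      tab$significant <- tab$p_value < alpha
    }
    tab
  }
  table2 <- mark(table2)
  table3 <- mark(table3)
  table4 <- mark(table4)

  sig_params <- if (nrow(table2)) {
    intersect(table2$parameter[table2$significant], params)
  } else {
    character(0)
  }
  roc_objects <- list()
  roc_tab <- purrr::map(sig_params, function(p) {
    r <- tryCatch(
      roc_analysis(cohort, p, positive_class = "IV",
                   ci_method = roc_ci_method),
      error = function(e) {
        message(sprintf("build_tables: ROC of %s failed: %s",
                        p, conditionMessage(e)))
        NULL
      })
    if (is.null(r)) return(NULL)
    roc_objects[[p]] <<- r
    glance(r)
  }) |> dplyr::bind_rows()

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4,
       roc = roc_tab, roc_objects = roc_objects,
       config = tibble(alpha = alpha, gate_mode = gate_mode,
                       t_variant = t_variant, roc_ci_method = roc_ci_method,
                       multiplicity = multiplicity))
}

#' Reference group-level summary statistics
#'
#' Group means, SDs, sizes and published p-values for a reference
#' 56-patient high-grade-glioma cohort (11 WHO grade III, 45 grade IV; 21
#' MGMT-methylated vs 29 unmethylated, the MGMT group sizes inferred from
#' the published t-based confidence-interval half-widths since they are not
#' printed directly). ADC rows are in 1e-5 mm^2/s. These summaries serve as
#' inputs to [summary_ttest()] for checking the comparison machinery against
#' published group-level results without per-patient data.
#'
#' @param split `"grade"` or `"mgmt"`.
#' @return Tibble with `parameter`, group summaries and `published_p`.
#' @export
reference_group_summaries <- function(split = c("grade", "mgmt")) {
  split <- match.arg(split)
  path <- system.file("extdata", "reference_group_summaries.csv",
                      package = "adchist", mustWork = TRUE)
  d <- readr::read_csv(path, show_col_types = FALSE)
  d[d$split == split, setdiff(names(d), "split")]
}
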