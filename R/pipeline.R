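#' Run configuration for the pipeline commands
#'
#' Collects every knob that affects results so runs are auditable; the
#' analyze stage writes these values into a run-metadata JSON next to its
#' outputs.
#'
#' @param unit_scale_in Declared scale of input ADC files.
#' @param report_scale mm^2/s per reported ADC unit.
#' @param bin_count Histogram bins for mode/entropy.
#' @param alpha Significance / gate level.
#' @param gate_mode `"per_group"` or `"cohort_wide"` Shapiro-Wilk gating.
#' @param t_variant `"student"` or `"welch"`.
#' @param roc_ci_method `"hanley_mcneil"` or `"delong"`.
#' @param multiplicity `"none"` or `"holm"`.
#' @param rng_seed Seed for the simulate stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(unit_scale_in = "1e-6",
                       report_scale = default_report_scale(),
                       bin_count = 128L, alpha = 0.05,
                       gate_mode = c("per_group", "cohort_wide"),
                       t_variant = c("student", "welch"),
                       roc_ci_method = c("hanley_mcneil", "delong"),
                       multiplicity = c("none", "holm"),
                       rng_seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "adchist_validation_error")
  }
  if (bin_count < 2) {
    abort("`bin_count` must be >= 2.", class = "adchist_validation_error")
  }
  unit_scale_factor(unit_scale_in)
  structure(list(
    unit_scale_in = unit_scale_in, report_scale = report_scale,
    bin_count = as.integer(bin_count), alpha = alpha,
    gate_mode = match.arg(gate_mode), t_variant = match.arg(t_variant),
    roc_ci_method = match.arg(roc_ci_method),
    multiplicity = match.arg(multiplicity),
    rng_seed = as.integer(rng_seed)
  ), class = "run_config")
}

#' Extract histogram profiles from ADC/mask file pairs
#'
#' Chains volume reading, mask resampling onto the ADC grid, voxel-sample
#' extraction and histogram profiling for each patient; per-patient
#' failures are reported and skipped.
#'
#' @param adc_paths NIfTI files or DICOM directories, one per patient.
#' @param mask_paths NIfTI mask files, parallel to `adc_paths`.
#' @param patient_ids Ids (default: ADC file stems).
#' @param config A [run_config()].
#' @param out_csv Optional path; if given, the table is also written there.
#' @return Profile tibble (one row per successfully processed patient).
#' @export
run_extract <- function(adc_paths, mask_paths, patient_ids = NULL,
                        config = run_config(), out_csv = NULL) {
  if (length(adc_paths) == 0L) {
    abort("No input volumes given.", class = "adchist_validation_error")
  }
  if (length(adc_paths) != length(mask_paths)) {
    abort("`adc_paths` and `mask_paths` must have equal length.",
          class = "adchist_validation_error")
  }
  ids <- patient_ids %||%
    tools::file_path_sans_ext(basename(adc_paths), compression = TRUE)
  rows <- purrr::pmap(list(adc_paths, mask_paths, ids), function(ap, mp, id) {
    tryCatch({
      adc <- read_adc(ap, unit_scale = config$unit_scale_in)
      mask <- resample_mask(read_mask(mp), adc)
      s <- extract_sample(adc, mask)
      message(sprintf("%s: %d voxels (%d excluded)",
                      id, s$n_voxels, s$n_excluded))
      dplyr::bind_cols(tibble(patient_id = id),
                       compute_profile(s, bin_count = config$bin_count,
                                       report_scale = config$report_scale))
    }, error = function(e) {
      warning(sprintf("Skipping %s: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    abort("Every input pair failed to process.", class = "adchist_io_error")
  }
  if (!is.null(out_csv)) write_profiles_csv(out, out_csv)
  out
}

#' Run the full statistical analysis and write its report files
#'
#' @param features A cohort tibble, or path to a feature/label CSV
#'   ([read_cohort_csv()] schema).
#' @param out_dir Output directory: `table1.csv` .. `table4.csv`,
#'   `roc.csv`, per-parameter `roc_points_<parameter>.csv`, boxplot/ROC
#'   figures (PDF) and `run_metadata.json`.
#' @param config A [run_config()].
#' @param figures Whether to write the PDF figures.
#' @return The [build_tables()] result, invisibly.
#' @export
run_analyze <- function(features, out_dir, config = run_config(),
                        figures = TRUE) {
  cohort <- if (is.character(features)) read_cohort_csv(features)
            else validate_cohort(features)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- build_tables(cohort, alpha = config$alpha,
                      gate_mode = config$gate_mode,
                      t_variant = config$t_variant,
                      roc_ci_method = config$roc_ci_method,
                      multiplicity = config$multiplicity)
  for (nm in c("table1", "table2", "table3", "table4", "roc")) {
    tab <- res[[nm]]
    if (is.data.frame(tab) && nrow(tab) > 0) {
      readr::write_csv(tab, file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  for (p in names(res$roc_objects)) {
    readr::write_csv(res$roc_objects[[p]]$curve,
                     file.path(out_dir, sprintf("roc_points_%s.csv", p)))
  }
  meta <- unclass(config)
  meta$n_patients <- nrow(cohort)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (figures) {
    grDevices::pdf(file.path(out_dir, "boxplots.pdf"), width = 10, height = 8)
    print(plot_parameter_boxplots(cohort))
    grDevices::dev.off()
    if (length(res$roc_objects)) {
      grDevices::pdf(file.path(out_dir, "roc_curves.pdf"), width = 5,
                     height = 5.5)
      for (r in res$roc_objects) print(autoplot(r))
      grDevices::dev.off()
    }
  }
  invisible(res)
}

#' Generate a synthetic fixture set (pipeline wrapper)
#'
#' @param out_dir Output directory.
#' @param config A [run_config()] (its `rng_seed` seeds the generator).
#' @param cfg Optional [synthetic_config()] override; by default one is
#'   built from `config$rng_seed`.
#' @param volumes Whether to render NIfTI volume/mask pairs.
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(out_dir, config = run_config(), cfg = NULL,
                         volumes = TRUE) {
  cfg <- cfg %||% synthetic_config(rng_seed = config$rng_seed)
  write_fixture_set(cfg, out_dir, volumes = volumes)
}
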