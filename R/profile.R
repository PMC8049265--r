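#' Thirteen whole-lesion ADC histogram parameters
#'
#' Computes the standard first-order statistics (mean, minimum, maximum,
#' 10th/25th/75th/90th percentiles, median, mode, standard deviation) and
#' second-order histogram statistics (skewness, kurtosis, entropy) of a
#' masked voxel sample.
#'
#' Conventions, each deliberate because implementations differ:
#' * Percentiles: linear interpolation between order statistics
#'   (`quantile(type = 7)`).
#' * SD: sample standard deviation, denominator n-1.
#' * Skewness: biased moment coefficient m3 / m2^(3/2).
#' * Kurtosis: Pearson (non-excess) m4 / m2^2, so a Gaussian gives 3.
#' * Mode and entropy come from an equal-width histogram with `bin_count`
#'   bins spanning the sample's own \[min, max\]; the mode is the centre of
#'   the fullest bin (ties go to the lowest-value bin) and entropy is
#'   -sum(p log2 p) over non-empty bins, in bits. These two are the only
#'   binning-dependent outputs, and `bin_count` is recorded alongside them.
#'
#' A zero-variance sample has no defined skewness/kurtosis: those fields are
#' `NA` with a warning, while mode (= the constant) and entropy (= 0) are
#' still returned.
#'
#' @param sample A [voxel_sample()] (or bare numeric vector, mm^2/s) with at
#'   least 2 voxels.
#' @param bin_count Number of equal-width histogram bins (default 128).
#' @param report_scale mm^2/s per reported unit for the ADC-valued fields
#'   (default 1e-5, so 1.3757e-3 mm^2/s reports as 137.57).
#' @return A one-row tibble with columns `ADCmean`, `ADCmin`, `ADCmax`,
#'   `ADCp10`, `ADCp25`, `ADCp75`, `ADCp90`, `ADCmedian`, `ADCmode`, `ADCsd`
#'   (all in report units), `Kurtosis`, `Skewness`, `Entropy`, `n_voxels`,
#'   `bin_count`.
#' @export
#' @examples
#' compute_profile(voxel_sample(c(1, 2, 3, 4, 5) * 1e-5))
compute_profile <- function(sample, bin_count = 128L,
                            report_scale = default_report_scale()) {
  if (is.numeric(sample)) sample <- voxel_sample(sample)
  stopifnot(inherits(sample, "voxel_sample"))
  if (!is.numeric(bin_count) || bin_count < 2) {
    abort("`bin_count` must be an integer >= 2.",
          class = "adchist_validation_error")
  }
  bin_count <- as.integer(bin_count)
  v <- sample$values
  n <- length(v)
  if (n < 2L) {
    abort("Histogram profiling needs at least 2 voxels.",
          class = "adchist_degenerate_sample")
  }

  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    warn("Zero-variance sample: skewness and kurtosis are undefined.",
         class = "adchist_zero_variance")
    skew <- NA_real_
    kurt <- NA_real_
  }

  h <- bin_histogram(v, bin_count)
  q <- unname(quantile(v, c(0.10, 0.25, 0.75, 0.90), type = 7))

  tibble(
    ADCmean   = to_report_units(m, report_scale),
    ADCmin    = to_report_units(min(v), report_scale),
    ADCmax    = to_report_units(max(v), report_scale),
    ADCp10    = to_report_units(q[1], report_scale),
    ADCp25    = to_report_units(q[2], report_scale),
    ADCp75    = to_report_units(q[3], report_scale),
    ADCp90    = to_report_units(q[4], report_scale),
    ADCmedian = to_report_units(median(v), report_scale),
    ADCmode   = to_report_units(h$mode, report_scale),
    ADCsd     = to_report_units(sd(v), report_scale),
    Kurtosis  = kurt,
    Skewness  = skew,
    Entropy   = h$entropy,
    n_voxels  = n,
    bin_count = bin_count
  )
}

# equal-width histogram over [min, max]; right-closed final bin
bin_histogram <- function(v, bin_count) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    return(list(mode = lo, entropy = 0,
                counts = c(length(v), rep(0L, bin_count - 1L))))
  }
  idx <- pmin(floor((v - lo) / (hi - lo) * bin_count) + 1L, bin_count)
  counts <- tabulate(idx, nbins = bin_count)
  width <- (hi - lo) / bin_count
  mode_bin <- which.max(counts) # first maximum = lowest-value bin on ties
  p <- counts[counts > 0] / length(v)
  list(mode = lo + (mode_bin - 0.5) * width,
       entropy = -sum(p * log2(p)),
       counts = counts)
}

#' Profile a cohort of voxel samples
#'
#' @param samples Named list of [voxel_sample()] objects (names are patient
#'   ids), or a list of `list(patient_id =, sample =)` pairs.
#' @inheritParams compute_profile
#' @return A tibble with `patient_id` followed by the profile columns, one
#'   row per patient in input order.
#' @export
profile_cohort <- function(samples, bin_count = 128L,
                           report_scale = default_report_scale()) {
  if (length(samples) == 0L) {
    abort("`samples` must be non-empty.", class = "adchist_validation_error")
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    abort("`samples` must be a named list (names are patient ids).",
          class = "adchist_validation_error")
  }
  ids <- names(samples)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate patient id(s): %s.",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "adchist_validation_error")
  }
  purrr::map2(ids, samples, function(id, s) {
    dplyr::bind_cols(tibble(patient_id = id),
                     compute_profile(s, bin_count, report_scale))
  }) |>
    dplyr::bind_rows()
}

#' Write a cohort profile table to CSV
#'
#' Column order and names follow the conventional reporting layout
#' (`patient_id`, the 13 parameters, `n_voxels`, `bin_count`); ADC columns
#' are in report units (default 1e-5 mm^2/s).
#'
#' @param profiles Tibble from [profile_cohort()] (extra label columns such
#'   as `who_grade`, `ki67`, `mgmt` are carried through after the standard
#'   block).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  std <- c("patient_id", adc_parameter_names(), "n_voxels", "bin_count")
  missing <- setdiff(std, names(profiles))
  if (length(missing)) {
    abort(sprintf("Profile table lacks column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "adchist_validation_error")
  }
  extra <- setdiff(names(profiles), std)
  readr::write_csv(profiles[, c(std, extra)], path)
  invisible(path)
}

#' Names of the 13 histogram parameters, in reporting order
#' @return Character vector.
#' @export
adc_parameter_names <- function() {
  c("ADCmean", "ADCmin", "ADCmax", "ADCp10", "ADCp25", "ADCp75", "ADCp90",
    "ADCmedian", "ADCmode", "ADCsd", "Kurtosis", "Skewness", "Entropy")
}
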