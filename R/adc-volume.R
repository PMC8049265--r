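#' Construct an ADC volume
#'
#' An `adc_volume` is a 3-D grid of apparent diffusion coefficient values in
#' canonical mm^2/s together with a voxel-to-world affine. Finite voxels must
#' be non-negative after unit normalisation (ADC is a physical diffusivity);
#' non-finite voxels are tolerated here and excluded later at sampling time.
#'
#' @param voxels 3-D numeric array of ADC values in mm^2/s.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @param unit_scale_in Declared scale of the source data (see
#'   [unit_scale_factor()]); recorded for provenance.
#' @param source_voxels Optional array of the values exactly as stored in
#'   the source file, retained (for integer-valued sources) so that
#'   reporting back at the source scale is lossless; see [report_voxels()].
#' @return An object of class `adc_volume`.
#' @export
adc_volume <- function(voxels, affine = diag(4), unit_scale_in = "mm2/s",
                       source_voxels = NULL) {
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array.", class = "adchist_validation_error")
  }
  affine <- check_affine(affine)
  finite <- voxels[is.finite(voxels)]
  if (length(finite) && min(finite) < 0) {
    abort("ADC volume contains negative finite voxels after unit normalisation.",
          class = "adchist_validation_error")
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) {
    abort("Voxel spacing must be positive.", class = "adchist_validation_error")
  }
  structure(
    list(voxels = voxels, affine = affine, voxel_spacing = spacing,
         unit_scale_in = unit_scale_in, source_voxels = source_voxels),
    class = "adc_volume"
  )
}

# retain the stored array when it is integer-valued (the common clinical
# case), so unit round trips stay bit-exact
integral_source <- function(vox) {
  fin <- is.finite(vox)
  if (all(fin) && all(vox == round(vox)) && max(abs(vox)) < 2^31) {
    array(as.integer(vox), dim = dim(vox))
  } else {
    NULL
  }
}

#' Report a volume's voxel values at a chosen scale
#'
#' Converts the canonical mm^2/s voxels to `unit_scale` units. When the
#' requested scale equals the scale the volume was read with and the source
#' was integer-valued, the retained stored array is returned, making the
#' round trip lossless (naive decimal rescaling of doubles can lose a ULP).
#'
#' @param x An [adc_volume()].
#' @param unit_scale Target scale (see [unit_scale_factor()]).
#' @return Numeric array in `unit_scale` units.
#' @export
report_voxels <- function(x, unit_scale = x$unit_scale_in) {
  stopifnot(inherits(x, "adc_volume"))
  factor <- unit_scale_factor(unit_scale)
  if (!is.null(x$source_voxels) &&
      identical(factor, unit_scale_factor(x$unit_scale_in))) {
    return(array(as.numeric(x$source_voxels), dim = dim(x$source_voxels)))
  }
  x$voxels / factor
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine))) {
    abort("`affine` must be a finite 4x4 matrix.",
          class = "adchist_validation_error")
  }
  if (abs(det(affine)) < .Machine$double.eps^0.5) {
    abort("`affine` must be invertible.", class = "adchist_validation_error")
  }
  affine
}

#' @export
print.adc_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<adc_volume> %d x %d x %d voxels, spacing %s mm, source scale %s\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_spacing, 4), collapse = " x "),
              as.character(x$unit_scale_in)))
  invisible(x)
}

#' @export
dim.adc_volume <- function(x) dim(x$voxels)

#' Read an ADC map from NIfTI or a DICOM series directory
#'
#' Voxel values are converted to canonical mm^2/s using the declared
#' `unit_scale`. For a DICOM directory the slices of the single series it
#' contains are assembled in spatial order using their position metadata,
#' so a shuffled set of files yields the same grid as an ordered one.
#'
#' @param path A `.nii`/`.nii.gz` file or a directory holding one DICOM series.
#' @param unit_scale Declared scale of the stored values (see
#'   [unit_scale_factor()]).
#' @return An [adc_volume()].
#' @export
read_adc <- function(path, unit_scale = "1e-6") {
  factor <- unit_scale_factor(unit_scale)
  if (dir.exists(path)) {
    ser <- read_dicom_series(path)
    return(adc_volume(ser$voxels * factor, ser$affine,
                      unit_scale_in = unit_scale,
                      source_voxels = integral_source(ser$voxels)))
  }
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': no such file.", path),
          class = "adchist_io_error")
  }
  img <- RNifti::readNifti(path)
  stored <- strip_nifti_attrs(as.array(img))
  if (length(dim(stored)) == 2L) dim(stored) <- c(dim(stored), 1L)
  adc_volume(stored * factor, nifti_affine(img), unit_scale_in = unit_scale,
             source_voxels = integral_source(stored))
}

strip_nifti_attrs <- function(x) {
  array(as.numeric(x), dim = dim(x))
}

# RNifti xform maps 0-based voxel indices to world coordinates
nifti_affine <- function(img) {
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  aff
}

#' Write an ADC volume or mask to NIfTI
#'
#' @param x An [adc_volume()] or [lesion_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param unit_scale Scale at which to store ADC values (volumes only);
#'   storing at the scale a volume was read with reproduces integer sources
#'   exactly.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, unit_scale = "mm2/s") {
  vox <- if (inherits(x, "adc_volume")) report_voxels(x, unit_scale)
         else x$voxels
  img <- RNifti::asNifti(vox)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
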