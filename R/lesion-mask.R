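#' Construct a lesion mask
#'
#' A binary voxel mask selecting the whole-lesion volume of interest, with
#' its own voxel-to-world affine (the mask may be drawn on a different grid,
#' e.g. a T1-weighted series, and resampled onto the ADC grid later).
#'
#' @param voxels 3-D array; any nonzero finite value is foreground.
#' @param affine 4x4 voxel-to-world transform.
#' @param source_grid `"native"` or `"resampled"`.
#' @return An object of class `lesion_mask` with 0/1 integer voxels.
#' @export
lesion_mask <- function(voxels, affine = diag(4), source_grid = "native") {
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3-D array.", class = "adchist_validation_error")
  }
  affine <- check_affine(affine)
  bin <- array(0L, dim = dim(voxels))
  bin[is.finite(voxels) & voxels != 0] <- 1L
  if (sum(bin) == 0L) {
    abort("Mask has no foreground voxels.", class = "adchist_degenerate_mask")
  }
  structure(list(voxels = bin, affine = affine, source_grid = source_grid),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lesion_mask> %d x %d x %d grid, %d foreground voxels (%s)\n",
              d[1], d[2], d[3], sum(x$voxels), x$source_grid))
  invisible(x)
}

#' @export
dim.lesion_mask <- function(x) dim(x$voxels)

#' Read a lesion mask from NIfTI
#'
#' @param path A `.nii`/`.nii.gz` file; nonzero voxels are foreground.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': no such file.", path),
          class = "adchist_io_error")
  }
  img <- RNifti::readNifti(path)
  vox <- strip_nifti_attrs(as.array(img))
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  lesion_mask(vox, nifti_affine(img))
}

#' Resample a mask onto an ADC grid
#'
#' Maps every target voxel centre through the composed affines
#' (world = A_adc x index; index_mask = A_mask^-1 x world) and takes the
#' nearest-neighbour mask value, so a binary mask stays binary. Already
#' co-registered masks (same grid and affine) pass through unchanged.
#'
#' @param mask A [lesion_mask()].
#' @param target An [adc_volume()] defining the output grid.
#' @return A [lesion_mask()] on the target grid with `source_grid = "resampled"`.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(target, "adc_volume"))
  td <- dim(target$voxels)
  if (identical(dim(mask$voxels), td) &&
      max(abs(mask$affine - target$affine)) < 1e-6) {
    out <- mask
    out$source_grid <- "resampled"
    return(out)
  }
  md <- dim(mask$voxels)
  # all target voxel centres, 0-based indices
  idx <- as.matrix(expand.grid(i = seq_len(td[1]) - 1,
                               j = seq_len(td[2]) - 1,
                               k = seq_len(td[3]) - 1))
  compose <- solve(mask$affine) %*% target$affine
  src <- t(compose %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
  src <- round(src)
  inside <- src[, 1] >= 0 & src[, 1] < md[1] &
            src[, 2] >= 0 & src[, 2] < md[2] &
            src[, 3] >= 0 & src[, 3] < md[3]
  vals <- integer(nrow(src))
  lin <- src[inside, 1] + md[1] * (src[inside, 2] + md[2] * src[inside, 3]) + 1
  vals[inside] <- mask$voxels[lin]
  out <- array(vals, dim = td)
  if (sum(out) == 0L) {
    abort("Resampled mask is empty: the lesion lies outside the ADC field of view.",
          class = "adchist_degenerate_mask")
  }
  structure(list(voxels = out, affine = target$affine,
                 source_grid = "resampled"),
            class = "lesion_mask")
}

#' Extract the masked voxel sample for histogram profiling
#'
#' Collects the ADC values of all mask-foreground voxels. Non-finite voxels
#' (and any negative ones, which cannot occur in a validated volume but are
#' guarded against) are dropped and counted; zeros are kept, since true
#' near-zero ADC occurs in dense or artefactual lesion cores and dropping
#' them would bias the lesion minimum upwards.
#'
#' @param adc An [adc_volume()].
#' @param mask A [lesion_mask()] on the same grid.
#' @return An object of class `voxel_sample`: list with `values` (mm^2/s),
#'   `n_voxels` and `n_excluded`.
#' @export
extract_sample <- function(adc, mask) {
  stopifnot(inherits(adc, "adc_volume"), inherits(mask, "lesion_mask"))
  if (!identical(dim(adc$voxels), dim(mask$voxels))) {
    abort("Mask is not on the ADC grid; call resample_mask() first.",
          class = "adchist_validation_error")
  }
  vals <- adc$voxels[mask$voxels == 1L]
  keep <- is.finite(vals) & vals >= 0
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("extract_sample: excluded %d non-finite/negative voxels.",
                    n_excluded))
  }
  vals <- vals[keep]
  if (length(vals) == 0L) {
    abort("All mask-foreground voxels are non-finite.",
          class = "adchist_degenerate_sample")
  }
  voxel_sample(vals, n_excluded = n_excluded)
}

#' Construct a voxel sample directly from values
#'
#' @param values Numeric vector of ADC values in mm^2/s (finite, >= 0).
#' @param n_excluded Count of voxels removed before this sample was formed.
#' @return A `voxel_sample`.
#' @export
voxel_sample <- function(values, n_excluded = 0L) {
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values)) || any(values < 0)) {
    abort("A voxel sample needs >= 1 finite non-negative value.",
          class = "adchist_validation_error")
  }
  structure(list(values = values, n_voxels = length(values),
                 n_excluded = as.integer(n_excluded)),
            class = "voxel_sample")
}

#' @export
print.voxel_sample <- function(x, ...) {
  cat(sprintf("<voxel_sample> %d voxels (%d excluded), mean %.4g mm^2/s\n",
              x$n_voxels, x$n_excluded, mean(x$values)))
  invisible(x)
}
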