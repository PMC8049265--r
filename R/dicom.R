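# Minimal DICOM support: uncompressed single-frame grayscale slices in
# implicit or explicit VR little endian, enough to ingest an exported ADC
# series (pixel grid, geometry, rescale) and to write synthetic fixtures.
# Undefined-length sequences are not supported.

DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"
DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a DICOM series directory as a voxel grid
#'
#' All `.dcm` files (any non-directory file is tried) must belong to one
#' series; slices are sorted by the projection of ImagePositionPatient onto
#' the slice normal, so file naming and ordering are irrelevant.
#'
#' @param dir Directory containing the slices of a single series.
#' @return A list with `voxels` (3-D array, rescale slope/intercept applied),
#'   `affine` (4x4 voxel-to-world, 0-based indices) and `series_uid`.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    abort(sprintf("No DICOM files found in '%s'.", dir),
          class = "adchist_io_error")
  }
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, function(s) s$series_uid %||% "", "")
  if (length(unique(uids)) > 1L) {
    abort(sprintf("Directory '%s' contains %d distinct series; expected one.",
                  dir, length(unique(uids))),
          class = "adchist_format_error")
  }
  orient <- slices[[1]]$orientation
  r <- orient[1:3]; cvec <- orient[4:6]
  normal <- c(r[2] * cvec[3] - r[3] * cvec[2],
              r[3] * cvec[1] - r[1] * cvec[3],
              r[1] * cvec[2] - r[2] * cvec[1])
  pos <- vapply(slices, function(s) sum(s$position * normal), 0)
  ord <- order(pos)
  slices <- slices[ord]

  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows; nz <- length(slices)
  same <- vapply(slices, function(s) s$cols == nx && s$rows == ny, TRUE)
  if (!all(same)) {
    abort("Slices in the series disagree on matrix size.",
          class = "adchist_format_error")
  }
  vox <- array(NA_real_, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) vox[, , k] <- slices[[k]]$pixels
  spacing <- slices[[1]]$pixel_spacing # c(row spacing, column spacing)
  if (nz > 1L) {
    step <- slices[[2]]$position - slices[[1]]$position
  } else {
    step <- normal * (slices[[1]]$slice_thickness %||% 1)
  }
  affine <- diag(4)
  affine[1:3, 1] <- r * spacing[2]
  affine[1:3, 2] <- cvec * spacing[1]
  affine[1:3, 3] <- step
  affine[1:3, 4] <- slices[[1]]$position
  list(voxels = vox, affine = affine,
       series_uid = slices[[1]]$series_uid %||% NA_character_)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw)
  explicit <- TRUE
  pos <- 1L
  if (n > 132L && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
    # file meta group (0002) is always explicit VR LE; its length tells us
    # where the dataset starts, and its transfer syntax how to parse it.
    meta <- parse_elements(raw, pos, explicit = TRUE, stop_after_group2 = TRUE)
    pos <- meta$pos
    ts <- meta$elements[["0002,0010"]]
    if (!is.null(ts)) {
      ts <- trimws(rawToChar(ts))
      ts <- gsub("\\x00", "", ts, useBytes = TRUE)
      if (ts == DICOM_IMPLICIT_LE) explicit <- FALSE
      else if (ts != DICOM_EXPLICIT_LE) {
        abort(sprintf("Unsupported transfer syntax '%s' in '%s'.", ts, path),
              class = "adchist_format_error")
      }
    }
  } else {
    # headerless stream: sniff explicit VR from the first element
    vrb <- raw[5:6]
    explicit <- all(vrb >= as.raw(65L) & vrb <= as.raw(90L))
  }
  parsed <- parse_elements(raw, pos, explicit = explicit)
  el <- parsed$elements

  need <- function(tag, what) {
    if (is.null(el[[tag]])) {
      abort(sprintf("DICOM file '%s' lacks required element %s (%s).",
                    path, tag, what),
            class = "adchist_format_error")
    }
    el[[tag]]
  }
  us <- function(x) readBin(x, "integer", n = 1, size = 2, signed = FALSE,
                            endian = "little")
  ds <- function(x) as.numeric(strsplit(trimws(rawToChar(x)), "\\\\")[[1]])

  rows <- us(need("0028,0010", "Rows"))
  cols <- us(need("0028,0011", "Columns"))
  bits <- if (is.null(el[["0028,0100"]])) 16L else us(el[["0028,0100"]])
  if (bits != 16L) {
    abort(sprintf("Only 16-bit pixel data supported (got %d bits).", bits),
          class = "adchist_format_error")
  }
  signed <- !is.null(el[["0028,0103"]]) && us(el[["0028,0103"]]) == 1L
  slope <- if (is.null(el[["0028,1053"]])) 1 else ds(el[["0028,1053"]])[1]
  inter <- if (is.null(el[["0028,1052"]])) 0 else ds(el[["0028,1052"]])[1]
  pix_raw <- need("7fe0,0010", "PixelData")
  vals <- readBin(pix_raw, "integer", n = rows * cols, size = 2,
                  signed = signed, endian = "little")
  if (!signed) vals[vals < 0] <- vals[vals < 0] + 65536L
  # PixelData runs column-index fastest; store as [column, row]
  pixels <- matrix(vals * slope + inter, nrow = cols, ncol = rows)

  list(
    pixels = pixels, rows = rows, cols = cols,
    position = ds(need("0020,0032", "ImagePositionPatient")),
    orientation = ds(need("0020,0037", "ImageOrientationPatient")),
    pixel_spacing = ds(need("0028,0030", "PixelSpacing")),
    slice_thickness = if (is.null(el[["0018,0050"]])) NULL
                      else ds(el[["0018,0050"]])[1],
    series_uid = if (is.null(el[["0020,000e"]])) NULL
                 else gsub("\\x00", "", trimws(rawToChar(el[["0020,000e"]])),
                           useBytes = TRUE)
  )
}

parse_elements <- function(raw, pos, explicit, stop_after_group2 = FALSE) {
  n <- length(raw)
  el <- list()
  u16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(raw[i:(i + 3L)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (stop_after_group2 && group != 2L) break
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (len < 0L) {
      abort("Undefined-length DICOM elements are not supported.",
            class = "adchist_format_error")
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (len > 0L) el[[tag]] <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    else el[[tag]] <- raw(0)
    pos <- pos + hdr + len
  }
  list(elements = el, pos = pos)
}

#' Write a voxel grid as a synthetic DICOM series
#'
#' Fixture writer for testing the DICOM ingestion path: emits one explicit
#' VR little endian file per slice with geometry, rescale and series metadata.
#' Values are stored as round(x / slope - intercept/slope) unsigned 16-bit.
#'
#' @param voxels 3-D array (stored-unit values; must fit in uint16 after
#'   rescaling).
#' @param dir Output directory (created if needed).
#' @param pixel_spacing c(row spacing, column spacing) in mm.
#' @param slice_origin World position of the first slice's first pixel.
#' @param slice_step World offset between consecutive slices.
#' @param orientation Direction cosines (row direction then column direction).
#' @param series_uid Series instance UID shared by the slices.
#' @param slope,intercept Rescale applied on read: value = stored*slope+intercept.
#' @param shuffle Permutation of slice file order (tests slice sorting).
#' @param prefix File name prefix for the written slices.
#' @return Character vector of written file paths, invisibly.
#' @export
write_synthetic_dicom_series <- function(voxels, dir,
                                         pixel_spacing = c(1, 1),
                                         slice_origin = c(0, 0, 0),
                                         slice_step = c(0, 0, 1),
                                         orientation = c(1, 0, 0, 0, 1, 0),
                                         series_uid = "1.2.826.0.1.999999.1",
                                         slope = 1, intercept = 0,
                                         shuffle = NULL, prefix = "slice") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nz <- dim(voxels)[3]
  file_order <- shuffle %||% seq_len(nz)
  stopifnot(length(file_order) == nz)
  paths <- character(nz)
  for (idx in seq_len(nz)) {
    k <- file_order[idx]
    pos <- slice_origin + (k - 1) * slice_step
    path <- file.path(dir, sprintf("%s_%03d.dcm", prefix, idx))
    write_dicom_slice(voxels[, , k], path, pixel_spacing, pos, orientation,
                      series_uid, sprintf("%s.%d", series_uid, k),
                      slope, intercept)
    paths[idx] <- path
  }
  invisible(paths)
}

write_dicom_slice <- function(slice, path, pixel_spacing, position,
                              orientation, series_uid, sop_uid,
                              slope, intercept) {
  stored <- round((slice - intercept) / slope)
  if (any(stored < 0 | stored > 65535)) {
    abort("Stored pixel values out of uint16 range; adjust slope/intercept.",
          class = "adchist_validation_error")
  }
  nx <- nrow(slice); ny <- ncol(slice) # nx = columns (fastest), ny = rows

  pad <- function(s, nul = FALSE) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, if (nul) as.raw(0) else charToRaw(" "))
    r
  }
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
  element <- function(group, elem, vr, value) {
    hdr <- c(u16raw(group), u16raw(elem), charToRaw(vr))
    if (vr %in% .long_vrs) {
      c(hdr, as.raw(c(0, 0)),
        writeBin(length(value), raw(), size = 4, endian = "little"), value)
    } else {
      c(hdr, u16raw(length(value)), value)
    }
  }
  ds_fmt <- function(x) pad(paste(vapply(x, function(v)
    formatC(v, format = "fg", digits = 10), ""), collapse = "\\"))

  # pixel data, column index fastest within each row: column-major order of
  # the [column, row] matrix is exactly that
  pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")

  dataset <- c(
    element(0x0008, 0x0016, "UI", pad("1.2.840.10008.5.1.4.1.1.4", nul = TRUE)),
    element(0x0008, 0x0018, "UI", pad(sop_uid, nul = TRUE)),
    element(0x0008, 0x0060, "CS", pad("MR")),
    element(0x0020, 0x000e, "UI", pad(series_uid, nul = TRUE)),
    element(0x0020, 0x0032, "DS", ds_fmt(position)),
    element(0x0020, 0x0037, "DS", ds_fmt(orientation)),
    element(0x0028, 0x0002, "US", u16raw(1)),
    element(0x0028, 0x0010, "US", u16raw(ny)),   # Rows
    element(0x0028, 0x0011, "US", u16raw(nx)),   # Columns
    element(0x0028, 0x0030, "DS", ds_fmt(pixel_spacing)),
    element(0x0028, 0x0100, "US", u16raw(16)),   # BitsAllocated
    element(0x0028, 0x0101, "US", u16raw(16)),
    element(0x0028, 0x0102, "US", u16raw(15)),
    element(0x0028, 0x0103, "US", u16raw(0)),    # unsigned
    element(0x0028, 0x1052, "DS", ds_fmt(intercept)),
    element(0x0028, 0x1053, "DS", ds_fmt(slope)),
    element(0x7fe0, 0x0010, "OW", pix)
  )
  meta <- c(
    element(0x0002, 0x0002, "UI", pad("1.2.840.10008.5.1.4.1.1.4", nul = TRUE)),
    element(0x0002, 0x0003, "UI", pad(sop_uid, nul = TRUE)),
    element(0x0002, 0x0010, "UI", pad(DICOM_EXPLICIT_LE, nul = TRUE))
  )
  group_len <- element(0x0002, 0x0000, "UL",
                       writeBin(length(meta), raw(), size = 4,
                                endian = "little"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, dataset), con)
  invisible(path)
}
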