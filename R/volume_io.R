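#' CT volume container
#'
#' A CT volume is a 3D scalar grid of Hounsfield units (HU) with physical
#' voxel spacing. The internal axis order is (slice, row, column), with
#' `spacing_mm` in the same order; all downstream geometry works in physical
#' millimetre coordinates, so the axis convention never reaches the results.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing_mm numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin_mm numeric length-3, physical position of voxel (1,1,1).
#' @param axis_order_note free-text record of the orientation convention.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                      axis_order_note = "(slice, row, column)") {
  if (length(dim(voxels)) != 3L)
    stop_hii("hii_format_error", sprintf(
      "a CT volume must have exactly 3 axes, got %d", length(dim(voxels))))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop_hii("hii_format_error", "spacing_mm must be 3 positive numbers")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), axis_order_note = axis_order_note),
    class = "ct_volume")
}

#' Binary mask aligned to a CT volume
#'
#' @param voxels 3D array with values in {0,1} (logical arrays are accepted).
#' @inheritParams ct_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop_hii("hii_format_error", "a mask must have exactly 3 axes")
  v <- array(as.integer(voxels), dim = dim(voxels))
  if (anyNA(v) || !all(v %in% c(0L, 1L)))
    stop_hii("hii_format_error", "mask values must be strictly in {0, 1}")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_hii("hii_format_error", "spacing_mm must be 3 positive numbers")
  structure(list(voxels = v, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume: %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask: %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$voxels), collapse = " x "), sum(x$voxels),
              paste(signif(x$spacing_mm, 4), collapse = " x ")))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1/2 file; voxel values are passed through unchanged
#' (assumed to already be in HU) and spacing is taken from the header pixdim.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    stop_hii("hii_io_error", sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_hii("hii_format_error", sprintf(
      "expected a 3D scalar volume, got %dD data (dim %s)",
      length(d), paste(d, collapse = "x")))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  ct_volume(array(as.numeric(img), dim = d), spacing_mm = sp,
            axis_order_note = "NIfTI storage order, orientation not applied")
}

#' Read a binary mask from NIfTI
#'
#' @inheritParams read_nifti
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_nifti(path)
  binary_mask(v$voxels != 0, v$spacing_mm, v$origin_mm)
}

.write_nifti_array <- function(voxels, spacing_mm, path, datatype) {
  attr(voxels, "pixdim") <- spacing_mm
  img <- RNifti::asNifti(voxels, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask as NIfTI
#'
#' Round trip through [read_mask()] reproduces voxels exactly and spacing to
#' header precision.
#'
#' @param mask a [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!dir.exists(dirname(path)))
    stop_hii("hii_io_error", sprintf("directory does not exist: %s",
                                     dirname(path)))
  .write_nifti_array(mask$voxels, mask$spacing_mm, path, "uint8")
}

#' Write a CT volume as NIfTI
#'
#' HU values are stored as 16-bit signed integers (lossless for integral HU).
#'
#' @param volume a [ct_volume()].
#' @param path output path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop_hii("hii_io_error", sprintf("directory does not exist: %s",
                                     dirname(path)))
  .write_nifti_array(volume$voxels, volume$spacing_mm, path, "int16")
}
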