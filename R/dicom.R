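# Minimal DICOM support: single-frame CT slices in the Explicit VR Little
# Endian transfer syntax. This is not a general DICOM implementation -- it
# covers what an axial CT series needs for HU-correct volume reconstruction:
# series identity, slice geometry, rescale tags and 16-bit pixel data.
# Sequences with undefined length and compressed syntaxes are rejected.

.EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_tag <- function(group, element) sprintf("%04X%04X", group, element)

.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  out <- list()
  n <- length(raw)
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L)
      body_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      body_at <- pos + 8L
    }
    if (len == 4294967295)
      stop_hii("hii_format_error", sprintf(
        "undefined-length element (%04x,%04x) not supported", group, element))
    tag <- .dcm_tag(group, element)
    if (tag %in% names(.DCM_WANTED)) {
      body <- raw[body_at:(body_at + len - 1L)]
      out[[tag]] <- .dcm_decode(vr, body)
    }
    pos <- body_at + len
  }
  ts <- out[[.dcm_tag(0x0002, 0x0010)]]
  if (!is.null(ts) && ts != .EXPLICIT_VR_LE)
    stop_hii("hii_format_error", sprintf(
      "unsupported transfer syntax '%s' in %s", ts, path))
  out
}

.DCM_WANTED <- local({
  tags <- list(
    c(0x0002, 0x0010), # TransferSyntaxUID
    c(0x0020, 0x000E), # SeriesInstanceUID
    c(0x0020, 0x0032), # ImagePositionPatient
    c(0x0028, 0x0010), # Rows
    c(0x0028, 0x0011), # Columns
    c(0x0028, 0x0030), # PixelSpacing
    c(0x0028, 0x0100), # BitsAllocated
    c(0x0028, 0x0103), # PixelRepresentation
    c(0x0028, 0x1052), # RescaleIntercept
    c(0x0028, 0x1053), # RescaleSlope
    c(0x7FE0, 0x0010)  # PixelData
  )
  out <- lapply(tags, function(t) t)
  names(out) <- vapply(tags, function(t) .dcm_tag(t[1], t[2]), "")
  out
})

.dcm_chr <- function(body) {
  # strip padding NULs before conversion (embedded NUL is illegal in R strings)
  sub(" +$", "", rawToChar(body[body != as.raw(0)]))
}

.dcm_decode <- function(vr, body) {
  switch(vr,
    UI = , LO = , SH = , CS = .dcm_chr(body),
    DS = as.numeric(strsplit(.dcm_chr(body), "\\\\")[[1]]),
    IS = as.integer(strsplit(rawToChar(body), "\\\\")[[1]]),
    US = readBin(body, "integer", n = length(body) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    OW = , OB = body,
    body)
}

#' Read an axial CT DICOM series
#'
#' Reads every file in `directory` as one single-series CT acquisition
#' (Explicit VR Little Endian), sorts slices by their position along the
#' slice axis, and converts stored values to HU via
#' `HU = stored * RescaleSlope + RescaleIntercept`. Missing rescale tags are
#' an error: guessing a slope silently shifts the whole HU window.
#'
#' @param directory path containing one DICOM file per slice.
#' @return A [ct_volume()] with axis order (slice, row, column); slice
#'   spacing is inferred from inter-slice positions and in-plane spacing
#'   from PixelSpacing.
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory))
    stop_hii("hii_io_error", sprintf("directory not found: %s", directory))
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop_hii("hii_io_error", sprintf("no files in %s", directory))
  slices <- lapply(files, .read_dicom_file)

  uids <- unique(vapply(slices, function(s)
    s[[.dcm_tag(0x0020, 0x000E)]] %||% NA_character_, ""))
  if (anyNA(uids))
    stop_hii("hii_format_error", "SeriesInstanceUID missing from a slice")
  if (length(uids) > 1L)
    stop_hii("hii_format_error", sprintf(
      "directory mixes %d series: %s", length(uids),
      paste(uids, collapse = ", ")))

  get1 <- function(s, g, e, what) {
    v <- s[[.dcm_tag(g, e)]]
    if (is.null(v))
      stop_hii("hii_format_error", sprintf("required tag %s missing", what))
    v
  }
  z <- vapply(slices, function(s)
    get1(s, 0x0020, 0x0032, "ImagePositionPatient")[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]

  rows <- get1(slices[[1]], 0x0028, 0x0010, "Rows")
  cols <- get1(slices[[1]], 0x0028, 0x0011, "Columns")
  px <- get1(slices[[1]], 0x0028, 0x0030, "PixelSpacing")
  bits <- get1(slices[[1]], 0x0028, 0x0100, "BitsAllocated")
  if (bits != 16L)
    stop_hii("hii_format_error", sprintf("only 16-bit pixel data supported, got %d", bits))
  signed <- get1(slices[[1]], 0x0028, 0x0103, "PixelRepresentation") == 1L

  nz <- length(slices)
  vox <- array(0, dim = c(nz, rows, cols))
  for (i in seq_len(nz)) {
    s <- slices[[i]]
    slope <- s[[.dcm_tag(0x0028, 0x1053)]]
    intercept <- s[[.dcm_tag(0x0028, 0x1052)]]
    if (is.null(slope) || is.null(intercept))
      stop_hii("hii_format_error",
               "RescaleSlope/RescaleIntercept missing; refusing to assume HU scaling")
    pd <- get1(s, 0x7FE0, 0x0010, "PixelData")
    stored <- readBin(pd, "integer", n = rows * cols, size = 2,
                      signed = signed, endian = "little")
    if (!signed) stored <- as.numeric(stored)
    # pixel data is row-major (rows of the image in sequence)
    vox[i, , ] <- matrix(stored * slope + intercept,
                         nrow = rows, ncol = cols, byrow = TRUE)
  }
  dz <- if (nz > 1L) stats::median(diff(z)) else 1
  if (nz > 1L && dz <= 0)
    stop_hii("hii_format_error", "slice positions are not strictly increasing")
  ct_volume(vox, spacing_mm = c(dz, px[1], px[2]),
            origin_mm = c(z[1], 0, 0),
            axis_order_note = "(slice, row, column) from sorted DICOM series")
}

.dcm_element <- function(group, element, vr, body) {
  if (is.character(body)) {
    body <- charToRaw(body)
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    if (length(body) %% 2L == 1L) body <- c(body, pad)
  }
  hdr <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                  size = 2, endian = "little")
  if (vr %in% .LONG_VRS) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

#' Write a CT volume as a synthetic DICOM series
#'
#' Writes one Explicit VR Little Endian file per slice with the geometry and
#' rescale tags that [read_dicom_series()] consumes. Intended for generating
#' test series from phantoms -- it emits the minimal tag set for a valid
#' round trip, not a clinically complete header.
#'
#' @param volume a [ct_volume()].
#' @param directory output directory (created if needed).
#' @param series_uid SeriesInstanceUID to stamp on every slice.
#' @param rescale_slope,rescale_intercept HU = stored * slope + intercept;
#'   stored values are computed from the volume's HU accordingly.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(volume, directory,
                               series_uid = "1.2.826.0.1.3680043.9999.1",
                               rescale_slope = 1,
                               rescale_intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  sp <- volume$spacing_mm
  paths <- character(d[1])
  for (i in seq_len(d[1])) {
    stored <- round((volume$voxels[i, , ] - rescale_intercept) / rescale_slope)
    if (any(stored < -32768 | stored > 32767))
      stop_hii("hii_format_error", "stored values exceed int16 range")
    pd <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
    meta <- .dcm_element(0x0002, 0x0010, "UI", .EXPLICIT_VR_LE)
    ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                            collapse = "\\")
    body <- c(
      .dcm_element(0x0020, 0x000E, "UI", series_uid),
      .dcm_element(0x0020, 0x0032, "DS",
                   ds(c(0, 0, volume$origin_mm[1] + (i - 1) * sp[1]))),
      .dcm_element(0x0028, 0x0010, "US",
                   writeBin(d[2], raw(), size = 2, endian = "little")),
      .dcm_element(0x0028, 0x0011, "US",
                   writeBin(d[3], raw(), size = 2, endian = "little")),
      .dcm_element(0x0028, 0x0030, "DS", ds(sp[2:3])),
      .dcm_element(0x0028, 0x0100, "US",
                   writeBin(16L, raw(), size = 2, endian = "little")),
      .dcm_element(0x0028, 0x0103, "US",
                   writeBin(1L, raw(), size = 2, endian = "little")),
      .dcm_element(0x0028, 0x1052, "DS", ds(rescale_intercept)),
      .dcm_element(0x0028, 0x1053, "DS", ds(rescale_slope)),
      .dcm_element(0x7FE0, 0x0010, "OW", pd)
    )
    paths[i] <- file.path(directory, sprintf("slice%03d.dcm", i))
    con <- file(paths[i], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(paths)
}
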