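#' Construct a calibrated CT slice
#'
#' @param pixels Numeric matrix of Hounsfield-unit values (finite).
#' @param pixel_spacing_mm Length-2 positive numeric, (row, col) spacing.
#' @param slice_height_mm Height of the slice above the volume's reference
#'   (lowest) plane, in mm.
#' @param patient_id Character scalar.
#' @return A `ct_slice` object.
#' @export
ct_slice <- function(pixels, pixel_spacing_mm, slice_height_mm,
                     patient_id = "unknown") {
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (any(!is.finite(pixels))) stop("HU values must be finite")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  stopifnot(length(pixel_spacing_mm) == 2, all(pixel_spacing_mm > 0),
            is.finite(slice_height_mm))
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 slice_height_mm = as.numeric(slice_height_mm),
                 patient_id = as.character(patient_id)),
            class = "ct_slice")
}

#' Construct a CT volume from slices
#'
#' Slices are sorted ascending by height; all must share grid dimensions and
#' pixel spacing, with strictly increasing heights.
#'
#' @param slices List of `ct_slice` objects.
#' @param slice_thickness_mm Positive scalar, through-plane extent attributed
#'   to each slice (used for volume integration).
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(slices, slice_thickness_mm) {
  stopifnot(is.list(slices), length(slices) > 0, slice_thickness_mm > 0)
  if (!all(vapply(slices, inherits, logical(1), "ct_slice")))
    stop("all elements must be ct_slice objects")
  h <- vapply(slices, `[[`, numeric(1), "slice_height_mm")
  slices <- slices[order(h)]
  h <- sort(h)
  if (any(diff(h) <= 0)) stop("slice heights must be strictly increasing")
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  sp <- vapply(slices, `[[`, numeric(2), "pixel_spacing_mm")
  if (any(dims != dims[, 1]) || any(sp != sp[, 1]))
    stop("all slices must share grid dimensions and pixel spacing")
  structure(list(slices = slices,
                 slice_thickness_mm = as.numeric(slice_thickness_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  h <- vapply(x$slices, `[[`, numeric(1), "slice_height_mm")
  cat(sprintf("ct_volume: %d slices of %dx%d px, heights %g..%g mm, patient %s\n",
              length(x$slices), d[1], d[2], min(h), max(h),
              x$slices[[1]]$patient_id))
  invisible(x)
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("ct_slice: %dx%d px at %g mm, spacing %g x %g mm, patient %s\n",
              nrow(x$pixels), ncol(x$pixels), x$slice_height_mm,
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$patient_id))
  invisible(x)
}

slice_heights <- function(volume)
  vapply(volume$slices, `[[`, numeric(1), "slice_height_mm")

#' Convert raw stored pixel values to Hounsfield units
#'
#' Standard CT calibration `HU = raw * slope + intercept`.
#'
#' @param raw Numeric matrix or vector of stored values.
#' @param slope Rescale slope (nonzero).
#' @param intercept Rescale intercept.
#' @return Same shape as `raw`, in HU.
#' @export
to_hounsfield <- function(raw, slope, intercept) {
  if (!is.finite(slope) || slope == 0) stop("rescale slope must be nonzero")
  raw * slope + intercept
}

# ---------------------------------------------------------------------------
# Portable text fixture format, one file per volume:
#   ictexture-ct 1
#   patient_id <id>
#   pixel_spacing_mm <row> <col>
#   slice_thickness_mm <t>
#   dims <n_slices> <rows> <cols>
#   slice <height_mm>
#   <cols numbers> x rows            (C order by rows, "%.17g" -- lossless
#                                     for doubles)
# ---------------------------------------------------------------------------

#' Write a CT volume to the package's text fixture format
#'
#' A self-describing plain-text container: one header, then per slice a
#' height line followed by the HU grid row by row, printed with 17
#' significant digits so the double-precision round trip is exact.
#'
#' @param volume A `ct_volume`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ct_fixture <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (length(volume$slices) == 0) stop("refusing to write an empty volume")
  s1 <- volume$slices[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ictexture-ct 1",
    paste("patient_id", s1$patient_id),
    paste("pixel_spacing_mm", sprintf("%.17g", s1$pixel_spacing_mm[1]),
          sprintf("%.17g", s1$pixel_spacing_mm[2])),
    paste("slice_thickness_mm", sprintf("%.17g", volume$slice_thickness_mm)),
    paste("dims", length(volume$slices), nrow(s1$pixels), ncol(s1$pixels))
  ), con)
  for (s in volume$slices) {
    writeLines(paste("slice", sprintf("%.17g", s$slice_height_mm)), con)
    writeLines(apply(s$pixels, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a CT volume from the text fixture format
#'
#' @param path Fixture file written by [write_ct_fixture()].
#' @return A `ct_volume`.
#' @export
read_ct_fixture <- function(path) {
  lines <- readLines(path)
  fail <- function(i, what) stop(sprintf(
    "malformed fixture %s at line %d: %s", path, i, what))
  if (length(lines) < 5) fail(length(lines), "truncated header")
  if (!identical(lines[1], "ictexture-ct 1")) fail(1, "bad magic line")
  fld <- function(i, key, n) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (parts[1] != key || length(parts) != n + 1)
      fail(i, paste("expected", key, "with", n, "values"))
    parts[-1]
  }
  pid <- fld(2, "patient_id", 1)
  spacing <- as.numeric(fld(3, "pixel_spacing_mm", 2))
  thick <- as.numeric(fld(4, "slice_thickness_mm", 1))
  dims <- as.integer(fld(5, "dims", 3))
  n_slices <- dims[1]; nr <- dims[2]; nc <- dims[3]
  i <- 6
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    if (i > length(lines)) fail(length(lines), "truncated: missing slice header")
    h <- as.numeric(fld(i, "slice", 1)); i <- i + 1
    if (i + nr - 1 > length(lines)) fail(length(lines), "truncated pixel rows")
    rows <- lines[i:(i + nr - 1)]; i <- i + nr
    vals <- scan(text = rows, quiet = TRUE)
    if (length(vals) != nr * nc) fail(i - 1, "wrong pixel count in slice")
    slices[[k]] <- ct_slice(matrix(vals, nr, nc, byrow = TRUE),
                            spacing, h, pid)
  }
  ct_volume(slices, thick)
}

# ---------------------------------------------------------------------------
# Minimal DICOM (explicit VR little endian, single-frame axial CT). Only the
# tags the package needs are read; a matching writer exists so the DICOM path
# is exercised end to end with synthetic series.
# ---------------------------------------------------------------------------

.dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

.dcm_write_element <- function(con, group, element, vr, value) {
  writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("OB", "OW")) {
    writeBin(as.integer(0), con, size = 2, endian = "little")
    writeBin(as.integer(length(value) * 2L), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
  } else if (vr == "US") {
    writeBin(as.integer(2L * length(value)), con, size = 2, endian = "little")
    writeBin(as.integer(value), con, size = 2, endian = "little")
  } else { # string VRs: UI, DS, IS, LO, CS
    s <- paste(value, collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    writeBin(as.integer(nchar(s)), con, size = 2, endian = "little")
    writeChar(s, con, nchars = nchar(s), eos = NULL)
  }
}

#' Write one slice of a synthetic DICOM CT series
#'
#' Explicit-VR little-endian, 16-bit signed pixels; used to exercise the
#' DICOM reading path without real scanner output. HU values must be
#' integers representable after the given rescale.
#'
#' @param slice A `ct_slice`.
#' @param path Output file.
#' @param series_uid Series Instance UID string shared by the series.
#' @param slope,intercept Rescale calibration; stored raw =
#'   `(HU - intercept)/slope`.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(slice, path, series_uid,
                              slope = 1, intercept = -1024) {
  stopifnot(inherits(slice, "ct_slice"))
  raw <- (slice$pixels - intercept) / slope
  if (max(abs(raw - round(raw))) > 1e-6)
    stop("HU values not representable as integers under this rescale")
  raw <- round(raw)
  if (any(raw < -32768 | raw > 32767)) stop("raw values exceed int16 range")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  w <- function(g, e, vr, v) .dcm_write_element(con, g, e, vr, v)
  w(0x0008, 0x0060, "CS", "CT")
  w(0x0010, 0x0020, "LO", slice$patient_id)
  w(0x0020, 0x000E, "UI", series_uid)
  w(0x0020, 0x0032, "DS", sprintf("%.10g", c(0, 0, slice$slice_height_mm)))
  w(0x0020, 0x0037, "DS", sprintf("%.10g", c(1, 0, 0, 0, 1, 0)))
  w(0x0028, 0x0010, "US", nrow(slice$pixels))
  w(0x0028, 0x0011, "US", ncol(slice$pixels))
  w(0x0028, 0x0030, "DS", sprintf("%.10g", slice$pixel_spacing_mm))
  w(0x0028, 0x0100, "US", 16)
  w(0x0028, 0x0103, "US", 1)
  w(0x0028, 0x1052, "DS", sprintf("%.10g", intercept))
  w(0x0028, 0x1053, "DS", sprintf("%.10g", slope))
  # pixel data, row-major (DICOM stores rows of the image consecutively)
  w(0x7FE0, 0x0010, "OW", as.vector(t(raw)))
  invisible(path)
}

#' Write a whole volume as a DICOM series directory
#'
#' @param volume A `ct_volume`.
#' @param dir Output directory (created if needed).
#' @param series_uid Series UID; a fixed synthetic default is used if omitted.
#' @inheritParams write_dicom_slice
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir, series_uid = "1.2.826.0.1.999999.1",
                               slope = 1, intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(volume$slices))
    write_dicom_slice(volume$slices[[k]],
                      file.path(dir, sprintf("slice%03d.dcm", k)),
                      series_uid, slope, intercept)
  invisible(dir)
}

.dcm_read_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 128)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "DICM"))
    stop(sprintf("%s is not a DICOM file (missing DICM magic)", path))
  el <- list()
  repeat {
    hdr <- readBin(con, "integer", 2, size = 2, endian = "little",
                   signed = FALSE)
    if (length(hdr) < 2) break
    vr <- readChar(con, 2, useBytes = TRUE)
    tag <- .dcm_tag(hdr[1], hdr[2])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
      if (vr == "OW") {
        el[[tag]] <- readBin(con, "integer", len / 2, size = 2,
                             endian = "little", signed = TRUE)
      } else {
        readBin(con, "raw", len)
      }
    } else {
      len <- readBin(con, "integer", 1, size = 2, endian = "little",
                     signed = FALSE)
      if (vr == "US") {
        el[[tag]] <- readBin(con, "integer", len / 2, size = 2,
                             endian = "little", signed = FALSE)
      } else {
        s <- readChar(con, len, useBytes = TRUE)
        el[[tag]] <- trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
      }
    }
    if (seek(con) >= sz) break
  }
  el
}

#' Read an axial CT DICOM series into a calibrated volume
#'
#' Reads every `.dcm` file in the directory, requires a single Series
#' Instance UID and rescale tags, converts stored values to HU, and sorts
#' slices ascending by z position; heights are reported relative to the
#' lowest slice.
#'
#' @param directory_path Directory containing one DICOM series.
#' @param slice_thickness_mm Through-plane thickness attributed to each slice
#'   (default: the median spacing between adjacent slices, or 1 for a single
#'   slice).
#' @return A `ct_volume`.
#' @export
read_dicom_series <- function(directory_path, slice_thickness_mm = NULL) {
  files <- list.files(directory_path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    stop(sprintf("no DICOM files found in %s", directory_path))
  parsed <- lapply(files, .dcm_read_file)
  uids <- unique(vapply(parsed, function(e) {
    u <- e[["0020,000E"]]
    if (is.null(u)) stop(sprintf("missing SeriesInstanceUID in %s",
                                 directory_path))
    u
  }, character(1)))
  if (length(uids) > 1)
    stop(sprintf("directory %s contains %d distinct series (ambiguous)",
                 directory_path, length(uids)))
  slices <- lapply(seq_along(parsed), function(k) {
    e <- parsed[[k]]
    need <- function(tag, what) {
      v <- e[[tag]]
      if (is.null(v)) stop(sprintf("missing %s tag in %s", what, files[k]))
      v
    }
    slope <- as.numeric(need("0028,1053", "RescaleSlope"))
    intercept <- as.numeric(need("0028,1052", "RescaleIntercept"))
    nr <- as.integer(need("0028,0010", "Rows"))
    nc <- as.integer(need("0028,0011", "Columns"))
    spacing <- as.numeric(need("0028,0030", "PixelSpacing"))
    pos <- as.numeric(need("0020,0032", "ImagePositionPatient"))
    raw <- need("7FE0,0010", "PixelData")
    if (length(raw) != nr * nc) stop(sprintf("pixel count mismatch in %s",
                                             files[k]))
    pid <- e[["0010,0020"]]
    if (is.null(pid)) pid <- "unknown"
    ct_slice(matrix(to_hounsfield(raw, slope, intercept), nr, nc,
                    byrow = TRUE),
             spacing, pos[3], pid)
  })
  z <- vapply(slices, `[[`, numeric(1), "slice_height_mm")
  base <- min(z)
  slices <- lapply(slices, function(s) {
    s$slice_height_mm <- s$slice_height_mm - base
    s
  })
  if (is.null(slice_thickness_mm)) {
    dz <- diff(sort(z))
    slice_thickness_mm <- if (length(dz)) stats::median(dz) else 1
  }
  ct_volume(slices, slice_thickness_mm)
}
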