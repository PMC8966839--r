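# Calibration, the text fixture container, and the minimal DICOM path.

test_that("raw-to-HU calibration is the standard affine transform", {
  expect_equal(to_hounsfield(0, 1, -1024), -1024)
  expect_equal(to_hounsfield(1074, 1, -1024), 50)
  expect_equal(to_hounsfield(512, 2, 0), 1024)
  expect_error(to_hounsfield(1, 0, 0), "slope")
})

test_that("volume construction enforces geometry invariants", {
  s <- function(h) make_slice(matrix(1, 4, 4), height = h)
  v <- ct_volume(list(s(20), s(0), s(10)), 1)
  expect_equal(slice_heights(v), c(0, 10, 20))  # sorted ascending
  expect_error(ct_volume(list(s(0), s(0)), 1), "strictly increasing")
  bad <- list(s(0), make_slice(matrix(1, 5, 5), height = 1))
  expect_error(ct_volume(bad, 1), "share")
  expect_error(ct_slice(matrix(NaN, 2, 2), 1, 0), "finite")
})

test_that("text fixture round trip is exact, including non-integer HU", {
  set.seed(7)
  mats <- replicate(3, matrix(rnorm(36, 30, 10), 6, 6), simplify = FALSE)
  v <- make_volume(mats, heights = c(0, 2.5, 7), spacing = 0.5,
                   thickness = 2.5, id = "rt")
  path <- withr::local_tempfile(fileext = ".ict")
  write_ct_fixture(v, path)
  v2 <- read_ct_fixture(path)
  expect_identical(lapply(v2$slices, `[[`, "pixels"),
                   lapply(v$slices, `[[`, "pixels"))
  expect_identical(slice_heights(v2), slice_heights(v))
  expect_identical(v2$slice_thickness_mm, v$slice_thickness_mm)
  expect_identical(v2$slices[[1]]$pixel_spacing_mm,
                   v$slices[[1]]$pixel_spacing_mm)
  expect_identical(v2$slices[[1]]$patient_id, "rt")
})

test_that("fixture reader rejects malformed input with context", {
  v <- flat_volume()
  path <- withr::local_tempfile(fileext = ".ict")
  write_ct_fixture(v, path)
  lines <- readLines(path)
  writeLines(lines[1:10], path)
  expect_error(read_ct_fixture(path), "line")
  writeLines(c("not-a-fixture", lines[-1]), path)
  expect_error(read_ct_fixture(path), "magic")
})

test_that("writing an empty volume is refused", {
  v <- flat_volume()
  v$slices <- list()
  expect_error(write_ct_fixture(v, tempfile()), "empty")
})

test_that("a synthetic DICOM series survives the write/read round trip", {
  set.seed(11)
  mats <- replicate(3, matrix(as.double(sample(-50:80, 64, TRUE)), 8, 8),
                    simplify = FALSE)
  v <- make_volume(mats, heights = c(0, 1, 2), spacing = 0.5, id = "dcm1")
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir)
  v2 <- read_dicom_series(dir)
  expect_identical(lapply(v2$slices, `[[`, "pixels"),
                   lapply(v$slices, `[[`, "pixels"))
  expect_equal(slice_heights(v2), c(0, 1, 2))
  expect_equal(v2$slices[[1]]$pixel_spacing_mm, c(0.5, 0.5))
  expect_identical(v2$slices[[1]]$patient_id, "dcm1")
})

test_that("slices shuffled on disk come back ordered by position", {
  mats <- lapply(c(2, 0, 1), function(k) matrix(k, 4, 4))
  dir <- withr::local_tempdir()
  # write files in shuffled height order under shuffled names
  for (i in seq_along(mats))
    write_dicom_slice(make_slice(mats[[i]], height = c(2, 0, 1)[i]),
                      file.path(dir, sprintf("z%d.dcm", i)),
                      series_uid = "1.2.3.4")
  v <- read_dicom_series(dir)
  expect_equal(slice_heights(v), c(0, 1, 2))
  expect_equal(sapply(v$slices, function(s) s$pixels[1, 1]), c(0, 1, 2))
})

test_that("a directory with two series UIDs is rejected as ambiguous", {
  dir <- withr::local_tempdir()
  write_dicom_slice(make_slice(matrix(0, 4, 4), height = 0),
                    file.path(dir, "a.dcm"), series_uid = "1.1")
  write_dicom_slice(make_slice(matrix(0, 4, 4), height = 1),
                    file.path(dir, "b.dcm"), series_uid = "1.2")
  expect_error(read_dicom_series(dir), "distinct series")
})

test_that("missing rescale tags are an error, not a silent default", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "a.dcm")
  write_dicom_slice(make_slice(matrix(0, 4, 4), height = 0), path,
                    series_uid = "1.1")
  # strip the RescaleIntercept element (tag 0028,1052) from the byte stream
  bytes <- readBin(path, "raw", file.info(path)$size)
  tagpat <- as.raw(c(0x28, 0x00, 0x52, 0x10))
  hit <- NULL
  for (k in seq_len(length(bytes) - 3))
    if (all(bytes[k:(k + 3)] == tagpat)) { hit <- k; break }
  len <- as.integer(bytes[hit + 6]) + 256L * as.integer(bytes[hit + 7])
  bytes <- bytes[-(hit:(hit + 7 + len))]
  writeBin(bytes, path)
  expect_error(read_dicom_series(dir), "RescaleIntercept")
})
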