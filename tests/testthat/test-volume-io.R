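# Readers/writers: round trips, slice ordering, rescale, error handling.

make_io_volume <- function() {
  cached("io_volume", generate_phantom(phantom_spec(
    volume_shape = c(48L, 44L, 18L), spacing = c(2, 2.2, 3),
    rv_semi_axes = c(16, 14, 18), lv_semi_axes = c(14, 13, 18),
    atrium_scale = 0, noise_sigma = 0))$volume)
}

test_that("NIfTI and MetaImage round trips are bit-identical", {
  vol <- make_io_volume()
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_volume(vol, nii)
  back <- load_volume(nii)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)

  mha <- withr::local_tempfile(fileext = ".mha")
  write_metaimage(vol, mha)
  back2 <- load_volume(mha)
  expect_identical(back2$voxels, vol$voxels)
  expect_equal(back2$spacing, vol$spacing, tolerance = 1e-12)
  expect_equal(back2$origin, vol$origin, tolerance = 1e-12)

  mhd <- file.path(withr::local_tempdir(), "vol.mhd")
  write_metaimage(vol, mhd)
  expect_identical(load_volume(mhd)$voxels, vol$voxels)
})

test_that("DICOM series round-trips with the rescale transform applied", {
  vol <- make_io_volume()
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_volume(dir)
  # pixels are stored as rescaled signed 16-bit integers
  expect_equal(back$voxels, round(vol$voxels), tolerance = 0)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  # stored values really are shifted by the intercept
  f <- list.files(dir, full.names = TRUE)[1]
  ds <- rvlvcad:::dcm_parse_file(f)
  expect_equal(rvlvcad:::dcm_num_values(ds[["00281052"]]), -1024)
})

test_that("slice order comes from position tags, not file names", {
  vol <- make_io_volume()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dicom_series(vol, d1)
  fs <- list.files(d1, full.names = TRUE)
  perm <- rev(seq_along(fs))
  file.copy(fs, file.path(d2, sprintf("scrambled_%03d.dcm", perm)))
  expect_identical(load_volume(d2)$voxels, load_volume(d1)$voxels)
})

test_that("loading is idempotent across formats", {
  vol <- make_io_volume()
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  dcm <- withr::local_tempdir()
  write_nifti_volume(vol, nii)
  write_dicom_series(vol, dcm)
  via_nifti <- load_volume(nii)
  via_dicom <- load_volume(dcm)
  # voxelwise identical up to the integer storage of DICOM pixels
  expect_equal(via_dicom$voxels, round(via_nifti$voxels), tolerance = 0)
})

test_that("inconsistent inter-slice gaps abort with the offending slice named", {
  vol <- make_io_volume()
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  fs <- sort(list.files(dir, full.names = TRUE))
  file.remove(fs[9])   # doubles one gap mid-stack
  expect_error(load_volume(dir), "inconsistent inter-slice gap.*slice_0010")
})

test_that("missing required tags are hard errors", {
  dir <- withr::local_tempdir()
  # hand-build a file without PixelSpacing
  el <- rvlvcad:::dcm_element
  body <- c(
    el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    el(0x0020, 0x0032, "DS", "0\\0\\0"),
    el(0x0028, 0x0010, "US", rvlvcad:::dcm_uint16(4)),
    el(0x0028, 0x0011, "US", rvlvcad:::dcm_uint16(4)),
    el(0x0028, 0x0100, "US", rvlvcad:::dcm_uint16(16)),
    el(0x7FE0, 0x0010, "OW", writeBin(integer(16), raw(), size = 2))
  )
  con <- file(file.path(dir, "bad.dcm"), "wb")
  writeBin(raw(128), con); writeBin(charToRaw("DICM"), con); writeBin(body, con)
  close(con)
  expect_error(load_volume(dir), "PixelSpacing")
})

test_that("unknown formats and missing files are rejected", {
  expect_error(load_volume("no/such/file.nii"), "no such file")
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a volume", tf)
  expect_error(load_volume(tf), "unrecognised")
})

test_that("case reports round-trip and omit the ratio when flagged", {
  vol <- make_io_volume()
  cal_rv <- make_caliper(9, c(20, 30, 25.5), c(60, 30, 25.5))
  cal_lv <- make_caliper(10, c(20, 50, 28.5), c(60, 50, 28.5))
  rep <- structure(list(
    rv_caliper = cal_rv, lv_caliper = cal_lv,
    ratio = cal_rv$length_mm / cal_lv$length_mm,
    flags = character(),
    septum_summary = list(point_mm = c(40, 40, 27), normal = c(1, 0, 0),
                          score = 9.5, low_confidence = FALSE),
    mean_hu = list(rv = 350, lv = 320),
    timings_s = list(detection = 1.0)
  ), class = "case_report")
  dir <- withr::local_tempdir()
  write_report(rep, vol, dir)
  back <- read_report(dir)
  expect_equal(back$ratio, 1.0, tolerance = 1e-12)
  expect_equal(back$rv_caliper$length_mm, 40, tolerance = 1e-9)
  expect_equal(unlist(back$rv_caliper$endpoints_mm[[1]]), c(20, 30, 25.5),
               tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "rv_caliper.png")))
  # mm and voxel coordinates are consistent
  vx <- unlist(back$rv_caliper$endpoints_voxel[[1]])
  expect_equal(as.numeric(rvlvcad:::index_to_world(vol, vx)), c(20, 30, 25.5),
               tolerance = 1e-9)

  flagged <- rep
  flagged$lv_caliper <- NULL; flagged$ratio <- NULL
  flagged$flags <- "caliper_failed_lv"
  dir2 <- withr::local_tempdir()
  write_report(flagged, vol, dir2)
  back2 <- read_report(dir2)
  expect_null(back2$ratio)
  expect_true("caliper_failed_lv" %in% unlist(back2$flags))
  expect_false(file.exists(file.path(dir2, "lv_caliper.png")))
})
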