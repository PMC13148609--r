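test_that("skeleton pre-declares full-size datasets and tracks fill state", {
  g <- scan_geometry(n_projections = 10L, detector_rows = 64L,
                     detector_cols = 64L)
  f <- withr::local_tempfile(fileext = ".h5")
  create_skeleton(f, g, n_flats = 2L, n_darks = 2L)

  expect_identical(ctpipe:::extract_dims(f, "exchange/data"),
                   c(64L, 64L, 10L))
  v <- validate_skeleton(f)
  expect_identical(v$missing_data, 10L)
  expect_false(v$complete)

  set.seed(1)
  stk <- array(sample.int(65536, 64 * 64 * 10, replace = TRUE) - 1L,
               c(64, 64, 10))
  fill_frames(f, stk[, , 1:5], 1:5, "data")
  expect_identical(validate_skeleton(f)$missing_data, 5L)

  fill_frames(f, stk[, , 6:10], 6:10, "data")
  fill_frames(f, array(1000L, c(64, 64, 2)), 1:2, "white")
  fill_frames(f, array(90L, c(64, 64, 2)), 1:2, "dark")
  expect_true(validate_skeleton(f)$complete)

  acq <- read_acquisition(f)
  expect_identical(acq$projections, stk)        # bit-exact round trip
  expect_equal(acq$geometry$angles_deg, g$angles_deg)

  expect_error(fill_frames(f, stk[, , 1], 11L, "data"), "extent")
  expect_error(create_skeleton(f, g), "overwrite")
})

test_that("invalid geometries are rejected", {
  expect_error(scan_geometry(n_projections = 3, angles_deg = c(0, 0, 1),
                             detector_rows = 4, detector_cols = 4),
               "increasing")
  expect_error(scan_geometry(n_projections = 2, angles_deg = c(0, 1),
                             detector_rows = 4, detector_cols = 4,
                             pixel_size_um = 0), "pixel_size")
  expect_error(scan_geometry(n_projections = 2, angles_deg = c(0),
                             detector_rows = 4, detector_cols = 4),
               "length")
})

test_that("volume writers round-trip data and spacing in every format", {
  vol <- recon_volume(array(seq_len(8 * 8 * 8) / 7, c(8, 8, 8)),
                      voxel_size_um = 6.5,
                      provenance = list(list(stage = "test", k = 1)))
  for (fmt in c("hdf5", "tiff_stack", "nifti", "nrrd")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "tiff_stack") "" else paste0(".", fmt))
    write_volume(vol, path, fmt)
    back <- read_volume(path, fmt)
    # values are committed to float32 on write
    expect_lt(max(abs(back$data - vol$data)), 2^-18)
    expect_equal(back$voxel_size_um, 6.5, tolerance = 1e-6)
  }
  expect_error(write_volume(vol, tempfile(), "vtk"), "supported")
  expect_error(read_volume(tempfile(), "dicom"), "supported")
})

test_that("a tiff stack holds one slice file per z plane", {
  vol <- recon_volume(array(runif(8 * 8 * 8), c(8, 8, 8)))
  d <- withr::local_tempfile()
  write_volume(vol, d, "tiff_stack")
  files <- list.files(d, pattern = "\\.tif$")
  expect_length(files, 8L)
  one <- tiff::readTIFF(file.path(d, files[1]))
  expect_identical(dim(one), c(8L, 8L))
})

test_that("hdf5 volumes carry provenance through a round trip", {
  vol <- recon_volume(array(0, c(4, 4, 2)), voxel_size_um = 2,
                      provenance = list(list(stage = "fbp", filter = "hann")))
  f <- withr::local_tempfile(fileext = ".h5")
  write_volume(vol, f, "hdf5")
  back <- read_volume(f, "hdf5")
  expect_equal(back$provenance[[1]]$stage, "fbp")
  expect_equal(back$provenance[[1]]$filter, "hann")
})
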