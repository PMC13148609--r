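fdk_fixture <- function(grid = 64L, n = 101L) {
  ang <- angle_grid(n)
  list(proj = lineint_stack(default_phantom(grid), ang, grid, grid),
       ang = ang, grid = grid)
}

test_that("FDK in the parallel limit equals stacked FBP", {
  fx <- fdk_fixture()
  g <- scan_geometry(n_projections = length(fx$ang), angles_deg = fx$ang,
                     detector_rows = fx$grid, detector_cols = fx$grid)
  vol <- fdk_volume(fx$proj, g)
  stacked <- array(0, dim(vol$data))
  for (r in seq_len(fx$grid))
    stacked[, , r] <- fbp_slice(extract_sinogram(fx$proj, fx$ang, r))
  rel <- rmse(vol$data, stacked) / sqrt(mean(stacked^2))
  expect_lt(rel, 1e-3)
  # central slice agrees to numerical round-off
  mid <- fx$grid %/% 2L
  expect_lt(max(abs(vol$data[, , mid] -
                      fbp_slice(extract_sinogram(fx$proj, fx$ang, mid)))),
            1e-6)
})

test_that("doubling the source distance halves the cone-weighting deviation", {
  fx <- fdk_fixture()
  mk <- function(R) scan_geometry(n_projections = length(fx$ang),
                                  angles_deg = fx$ang,
                                  detector_rows = fx$grid,
                                  detector_cols = fx$grid,
                                  source_sample_mm = R, pixel_size_um = 6.5)
  vp <- fdk_volume(fx$proj, mk(Inf))$data
  d1 <- rmse(fdk_volume(fx$proj, mk(5))$data, vp)
  d2 <- rmse(fdk_volume(fx$proj, mk(10))$data, vp)
  expect_gt(d1 / d2, 1.6)
  expect_lt(d1 / d2, 2.4)
})

test_that("a too-close source is rejected", {
  fx <- fdk_fixture(grid = 16L, n = 9L)
  g <- scan_geometry(n_projections = 9, angles_deg = fx$ang,
                     detector_rows = 16, detector_cols = 16,
                     source_sample_mm = 16 * 6.5 / 1000 / 4,
                     pixel_size_um = 6.5)
  expect_error(fdk_volume(fx$proj, g), "inside")
})

test_that("streaming slab output is bit-identical to the single pass", {
  acq <- sim_scan(grid = 64L, n_proj = 101L, rows = 64L)
  cfg <- list(reconstruction = list(cor_mode = "none"))
  single <- reconstruct_pipeline(acq, cfg)

  f4 <- withr::local_tempfile(fileext = ".h5")
  res <- reconstruct_streaming(acq, cfg,
                               max_memory_bytes = 16 * 64 * 64 * 8,
                               path = f4)
  expect_identical(res$n_slabs, 4L)
  slabbed <- read_volume(f4, "hdf5")
  expect_identical(slabbed$data, ctpipe:::as_float32(single$data))

  # a budget covering the full volume produces one slab, same bytes
  f1 <- withr::local_tempfile(fileext = ".h5")
  res1 <- reconstruct_streaming(acq, cfg,
                                max_memory_bytes = 65 * 64 * 64 * 8,
                                path = f1)
  expect_identical(res1$n_slabs, 1L)
  expect_identical(read_volume(f1, "hdf5")$data, slabbed$data)
})

test_that("streaming refuses secondary outputs and impossible budgets", {
  acq <- sim_scan(grid = 16L, n_proj = 9L, rows = 4L)
  expect_error(
    reconstruct_streaming(acq, list(), 1e9, tempfile(),
                          secondary_output = "binned"),
    "secondary")
  expect_error(
    reconstruct_streaming(acq, list(reconstruction = list(cor_mode = "none")),
                          max_memory_bytes = 16, path = tempfile()),
    "minimum")
})
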