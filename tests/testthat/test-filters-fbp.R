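test_that("filter responses match their closed forms at DC and Nyquist", {
  n <- 64L
  fN <- 0.5
  nyq <- n / 2 + 1L                                 # index of -Nyquist bin
  for (nm in c("ramlak", "shepp_logan", "cosine", "hamming", "hann")) {
    resp <- build_filter(filter_spec(nm), n)
    expect_identical(resp[1], 0)                    # response(0) = 0
  }
  expect_equal(build_filter(filter_spec("ramlak"), n)[nyq], fN)
  expect_equal(build_filter(filter_spec("hann"), n)[nyq], 0)
  expect_equal(build_filter(filter_spec("shepp_logan"), n)[nyq],
               fN * 2 / pi)
  expect_equal(build_filter(filter_spec("cosine"), n)[nyq], 0,
               tolerance = 1e-15)
  expect_equal(build_filter(filter_spec("hamming"), n)[nyq], fN * 0.08)
})

test_that("the ramp dominates every windowed filter pointwise", {
  n <- 128L
  ram <- build_filter(filter_spec("ramlak"), n)
  for (nm in c("shepp_logan", "cosine", "hamming", "hann"))
    expect_true(all(build_filter(filter_spec(nm), n) <= ram + 1e-15))
})

test_that("the cutoff zeroes the response above the requested fraction", {
  resp <- build_filter(filter_spec("ramlak", cutoff_frac = 0.5), 64L)
  f <- ctpipe:::fft_freqs(64L)
  expect_true(all(resp[abs(f) > 0.25 + 1e-9] == 0))
  expect_true(all(resp[abs(f) <= 0.25] == abs(f)[abs(f) <= 0.25]))
})

test_that("unknown filter names list the registry", {
  expect_error(filter_spec("butterworth"), "ramlak")
  expect_identical(
    sort(c("ramlak", "shepp_logan", "cosine", "hamming", "hann")),
    sort(intersect(list_filters(),
                   c("ramlak", "shepp_logan", "cosine", "hamming", "hann"))))
})

test_that("FBP recovers a uniform disc to 5% with the sampling-rule projection count", {
  grid <- 128L
  n <- min_projection_count(grid)
  s <- analytic_sinogram(disc_phantom(grid, radius = 0.25, mu = 1),
                         angle_grid(n), grid)
  sl <- fbp_slice(s)
  centre <- (grid + 1) / 2
  expect_lt(abs(sl[64, 64] - 1), 0.05)
  expect_lt(abs(mean(sl[60:69, 60:69]) - 1), 0.05)
})

test_that("FBP is exactly linear and maps empty sinograms to zero slices", {
  s <- analytic_sinogram(default_phantom(64), angle_grid(101), 64)
  one <- fbp_slice(s)
  two <- fbp_slice(sinogram(2 * s$values, s$angles_deg))
  expect_identical(two, 2 * one)
  zero <- fbp_slice(sinogram(matrix(0, 101, 64), angle_grid(101)))
  expect_identical(zero, matrix(0, 64, 64))
  expect_error(fbp_slice(sinogram(matrix(0, 1, 8), 0)), "angles")
})

test_that("phantom RMSE is non-increasing as projections approach the sampling rule", {
  grid <- 64L
  truth <- phantom_image(default_phantom(grid))
  counts <- c(13L, 25L, 50L, min_projection_count(grid))
  errs <- vapply(counts, function(n) {
    s <- analytic_sinogram(default_phantom(grid), angle_grid(n), grid)
    rmse(circle_mask(fbp_slice(s), 1), circle_mask(truth, 1))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("circle mask trims the field of view to the requested diameter", {
  ones <- matrix(1, 8, 8)
  m <- circle_mask(ones, 1.0)
  expect_identical(m[1, 1], 0)                      # corners outside
  expect_identical(m[4, 4], 1)                      # centre inside

  wide <- circle_mask(matrix(1, 1000, 1000), 0.98)
  centre_row <- wide[500, ]
  expect_equal(sum(centre_row > 0), 980, tolerance = 2)

  frac0 <- mean(circle_mask(matrix(1, 512, 512), 1.0) == 0)
  expect_equal(frac0, 1 - pi / 4, tolerance = 2 / 512)
})
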