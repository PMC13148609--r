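test_that("frame averaging is the per-pixel mean", {
  stk <- array(0, c(2, 2, 2))
  stk[, , 2] <- 2
  expect_equal(average_frames(stk), matrix(1, 2, 2))
  one <- matrix(runif(9), 3, 3)
  expect_equal(average_frames(array(one, c(3, 3, 1))), one)
  expect_error(average_frames(array(0, c(2, 2, 0))), "empty")
})

test_that("averaging suppresses Poisson noise at the 1/sqrt(n) rate", {
  set.seed(7)
  rate <- 400
  stk <- array(rpois(16 * 16 * 100, rate), c(16, 16, 100))
  m <- average_frames(stk)
  # per-pixel 3 sigma / sqrt(100) bound, allowing the expected ~0.3% tail
  within <- abs(m - rate) <= 3 * sqrt(rate) / sqrt(100)
  expect_gt(mean(within), 0.98)
})

test_that("flat/dark normalisation maps references to 1 and 0", {
  dark <- matrix(90, 8, 8)
  flat <- matrix(1000, 8, 8) + outer(1:8, 1:8)
  refs <- reference_images(dark, flat)
  expect_equal(flat_dark_correct(flat, refs),
               matrix(1, 8, 8), ignore_attr = TRUE)
  expect_equal(flat_dark_correct(dark, refs),
               matrix(0, 8, 8), ignore_attr = TRUE)
  expect_equal(flat_dark_correct((flat + dark) / 2, refs),
               matrix(0.5, 8, 8), ignore_attr = TRUE)
})

test_that("sample-free simulated frames normalise to 1 within 1%", {
  acq <- sim_scan(grid = 64L, n_proj = 4L, rows = 16L,
                  artefacts = artefact_model(poisson_scale = 50000,
                                             dark_noise_sd = 2, seed = 3))
  refs <- reference_images(acq$darks, acq$flats)
  # a flat frame with noise stands in for a sample-free projection
  free <- ctpipe:::sample_counts(ctpipe:::default_flat_profile(16, 64),
                                 artefact_model(poisson_scale = 50000,
                                                dark_noise_sd = 2, seed = 99))
  cor <- flat_dark_correct(free, refs)
  expect_lt(abs(mean(cor) - 1), 0.01)
})

test_that("degenerate flat/dark pixels are clamped and counted", {
  dark <- matrix(100, 4, 4)
  flat <- matrix(500, 4, 4)
  flat[2, 2] <- 100                               # zero denominator
  refs <- suppressWarnings(reference_images(dark, flat))
  out <- flat_dark_correct(matrix(300, 4, 4), refs)
  expect_identical(attr(out, "n_clamped"), 1L)
  expect_true(all(is.finite(out)))
})

test_that("planted defective pixels are detected exactly", {
  set.seed(11)
  darks <- array(rnorm(32 * 32 * 4, 100, 1), c(32, 32, 4))
  flats <- array(rnorm(32 * 32 * 4, 20000, 20), c(32, 32, 4))
  expect_identical(sum(detect_bad_pixels(darks, flats, k = 6)), 0L)

  hot <- sample.int(32 * 32, 10)
  for (k in 1:4) { f <- darks[, , k]; f[hot] <- f[hot] + 20 * 25
                   darks[, , k] <- f }
  mask <- detect_bad_pixels(darks, flats, k = 5)
  expect_identical(sort(which(mask)), sort(hot))

  # a dead pixel (flat response zero) is always flagged
  flats2 <- flats; for (k in 1:4) flats2[5, 5, k] <- 0
  expect_true(detect_bad_pixels(darks, flats2, k = 5)[5, 5])
})

test_that("pixel repair replaces only flagged pixels with local medians", {
  img <- matrix(5, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[3, 3] <- TRUE
  expect_equal(repair_pixels(img, mask), img)       # constant stays constant

  ramp <- outer(1:6, 1:6)
  ramp2 <- ramp; ramp2[3, 3] <- 999
  fixed <- repair_pixels(ramp2, mask)
  nb <- ramp[2:4, 2:4][-5]
  expect_equal(fixed[3, 3], median(nb))
  flagged <- which(mask)
  expect_equal(fixed[-flagged], ramp2[-flagged])    # untouched elsewhere

  expect_identical(repair_pixels(ramp2, matrix(FALSE, 6, 6)), ramp2)
})

test_that("threshold median filter removes impulses, keeps smooth content, and is idempotent", {
  img <- matrix(3.5, 9, 9)
  expect_equal(threshold_median_filter(img, 10), img)

  imp <- matrix(0, 9, 9); imp[5, 5] <- 100
  expect_equal(threshold_median_filter(imp, 10), matrix(0, 9, 9))

  ramp <- outer(1:9, 1:9) / 10
  expect_equal(threshold_median_filter(ramp, 5), ramp)

  set.seed(4)
  noisy <- matrix(rnorm(400), 20, 20)
  noisy[sample.int(400, 6)] <- 50
  once <- threshold_median_filter(noisy, 3)
  twice <- threshold_median_filter(once, 3)
  expect_identical(twice, once)
})

test_that("trimming crops consistently and subsamples angles with the stride", {
  acq <- sim_scan(grid = 32L, n_proj = 10L, rows = 8L)
  expect_identical(trim_acquisition(acq)$projections, acq$projections)

  t2 <- trim_acquisition(acq, projection_stride = 2L)
  expect_identical(dim(t2$projections)[3], 5L)
  expect_length(t2$geometry$angles_deg, 5L)
  expect_equal(t2$geometry$angles_deg, acq$geometry$angles_deg[c(1, 3, 5, 7, 9)])

  t3 <- trim_acquisition(acq, rows = 1:4)
  expect_identical(dim(t3$projections)[1], 4L)
  expect_identical(dim(t3$flats)[1], 4L)

  expect_error(trim_acquisition(acq, rows = 9:12), "bounds")
})
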