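test_that("analytic line integrals equal ellipse chord lengths", {
  disc <- disc_phantom(grid = 64L, radius = 0.5, mu = 2)
  s <- analytic_sinogram(disc, c(0, 45, 90), 64)
  # central ray: chord 2 * r * (n_cols / 2) pixels times mu
  expect_equal(max(s$values), 2 * 0.5 * 32 * 2, tolerance = 1e-2)
  # rays outside every shape integrate to zero
  expect_identical(s$values[1, 1], 0)
  expect_identical(s$values[1, 64], 0)
})

test_that("closed-form sinogram matches brute-force integration to 0.1%", {
  ph <- phantom_spec(data.frame(
    x0 = c(0, 0.2, -0.3), y0 = c(0, -0.1, 0.25),
    a = c(0.7, 0.25, 0.15), b = c(0.5, 0.12, 0.3),
    phi_deg = c(10, -30, 60), mu = c(1, 0.5, -0.4)),
    grid = c(64, 64))
  s <- analytic_sinogram(ph, c(0, 30, 77.5, 120), 64)
  det_centre <- (64 - 1) / 2
  for (ai in 1:4) for (j in c(10, 25, 32, 47)) {
    t_units <- (j - 1 - det_centre) / 32
    oracle <- brute_line_integral(ph, c(0, 30, 77.5, 120)[ai], t_units) * 32
    got <- s$values[ai, j]
    expect_lt(abs(got - oracle), 1e-3 * max(s$values))
  }
})

test_that("a fixed seed reproduces the acquisition bit for bit", {
  art <- artefact_model(poisson_scale = 40000, dark_noise_sd = 2,
                        bad_pixel_fraction = 0.001,
                        stripe_defects = list(list(column = 10, gain = 1.05)),
                        cor_offset_px = 1.5, seed = 77)
  a1 <- sim_scan(grid = 32L, n_proj = 8L, rows = 8L, artefacts = art)
  a2 <- sim_scan(grid = 32L, n_proj = 8L, rows = 8L, artefacts = art)
  expect_identical(a1$projections, a2$projections)
  expect_identical(a1$flats, a2$flats)
  expect_identical(a1$darks, a2$darks)
  expect_identical(a1$metadata$seed, 77L)
})

test_that("noise-free simulation inverts to the analytic sinogram within quantisation", {
  grid <- 64L
  n <- 25L
  acq <- sim_scan(grid = grid, n_proj = n, rows = 4L)
  refs <- reference_images(acq$darks, acq$flats)
  p <- negative_log(flat_dark_correct(acq$projections, refs))
  truth <- analytic_sinogram(default_phantom(grid), angle_grid(n), grid)
  recovered <- t(p[2, , ])
  # 16-bit quantisation of the transmitted intensity bounds the error
  expect_lt(max(abs(exp(-recovered) - exp(-truth$values))), 2 / 2^15)
})

test_that("planted artefacts are recoverable by their pipeline stages", {
  # COR offset -> find_cor
  acq <- sim_scan(grid = 128L, n_proj = 2L, rows = 16L,
                  artefacts = artefact_model(cor_offset_px = 3),
                  angles_deg = c(0, 180))
  refs <- reference_images(acq$darks, acq$flats)
  p <- negative_log(flat_dark_correct(acq$projections, refs))
  expect_lt(abs(find_cor(p[, , 1], p[, , 2])$offset_px - 3), 0.5)

  # bad pixels -> detection mask
  art <- artefact_model(poisson_scale = 50000, dark_noise_sd = 2,
                        bad_pixel_fraction = 0.002, seed = 5)
  acq2 <- sim_scan(grid = 64L, n_proj = 4L, rows = 32L, artefacts = art)
  mask <- detect_bad_pixels(acq2$darks, acq2$flats, k = 5)
  planted <- acq2$metadata$bad_pixel_index
  expect_gt(mean(mask[planted]), 0.9)              # nearly all recovered

  # stripes -> sinogram column deviation
  art3 <- artefact_model(stripe_defects = list(list(column = 20, gain = 1.2)),
                         seed = 6)
  acq3 <- sim_scan(grid = 64L, n_proj = 51L, rows = 4L, artefacts = art3)
  expect_identical(acq3$metadata$stripe_columns, 20)
})

test_that("polychromatic hardening produces cupping before correction", {
  ang <- angle_grid(101)
  disc <- disc_phantom(grid = 64L, radius = 0.6, mu = 0.03)
  g <- scan_geometry(n_projections = 101, angles_deg = ang,
                     detector_rows = 2, detector_cols = 64)
  acq <- simulate_acquisition(
    disc, g, artefact_model(hardening = list(w1 = 0.6, scale1 = 1.6,
                                             w2 = 0.4, scale2 = 0.55)),
    n_flats = 4, n_darks = 4)
  p <- negative_log(flat_dark_correct(acq$projections,
                                      reference_images(acq$darks, acq$flats)))
  sl <- fbp_slice(sinogram(t(p[1, , ]), ang))
  centre <- mean(sl[30:35, 30:35])
  edge <- mean(sl[32, c(14:17, 48:51)])
  expect_lt(centre, edge)
})

test_that("excessive intensities are rejected with advice", {
  bright <- function(rows, cols) matrix(70000, rows, cols)
  g <- scan_geometry(n_projections = 2, angles_deg = c(0, 90),
                     detector_rows = 4, detector_cols = 16)
  expect_error(
    simulate_acquisition(default_phantom(16), g,
                         artefact_model(flat_profile = bright)),
    "16-bit")
})

test_that("tiled simulations carry exact offsets and reassemble", {
  g <- scan_geometry(n_projections = 3, angles_deg = c(0, 45, 90),
                     detector_rows = 12, detector_cols = 120,
                     tiling = list(n_h = 2, n_v = 1,
                                   step_h_px = 50, step_v_px = 0))
  tl <- make_tiled_acquisition(default_phantom(120), g, overlap_px = 20)
  expect_identical(tl$offsets_px, c(0L, 50L))

  lay <- tile_layout(list(tl$tiles[[1]][, , 1] * 1.0,
                          tl$tiles[[2]][, , 1] * 1.0),
                     cbind(c(0, tl$offsets_px[2] - 2), c(0, 0)))
  res <- stitch_correlation(lay, search_radius_px = 5)
  expect_identical(res$offsets_px[2, 1], 50)
  expect_equal(res$mosaic, tl$full$projections[, , 1] * 1.0,
               tolerance = 1e-9)

  # 1x1 tiling is the full field
  g1 <- g; g1$tiling <- list(n_h = 1L, n_v = 1L, step_h_px = 0, step_v_px = 0)
  tl1 <- make_tiled_acquisition(default_phantom(120), g1, overlap_px = 20)
  expect_identical(tl1$tiles[[1]], tl1$full$projections)
})
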