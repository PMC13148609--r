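pp20 <- function(gamma = 100, z_mm = 100)
  phase_params(gamma = gamma, z_mm = z_mm, energy_keV = 20,
               pixel_size_um = 6.5)

test_that("TIE-Hom response is 1 at DC, bounded, and matches the closed form at Nyquist", {
  H <- tie_hom_filter(c(64, 64), pp20())
  expect_equal(H[1, 1], 1)
  expect_true(all(H > 0 & H <= 1))

  # gamma = 0 and z = 0 are both the identity filter
  expect_equal(tie_hom_filter(c(16, 16), pp20(gamma = 0)),
               matrix(1, 16, 16))
  expect_equal(tie_hom_filter(c(16, 16), pp20(z_mm = 0)),
               matrix(1, 16, 16))

  # H at the column Nyquist for gamma = 100, z = 0.1 m, 20 keV, 6.5 um
  lambda <- 1.239842e-9 / 20
  u_N <- 1 / (2 * 6.5e-6)
  expected <- 1 / (1 + pi * lambda * 0.1 * 100 * u_N^2)
  expect_equal(H[1, 33], expected, tolerance = 1e-12)
})

test_that("phase retrieval is the identity for gamma = 0 and preserves constants", {
  img <- exp(-phantom_image(default_phantom(64)))
  expect_equal(phase_retrieve(img, pp20(gamma = 0)), img,
               tolerance = 1e-10)
  flat <- matrix(0.8, 32, 32)
  expect_equal(phase_retrieve(flat, pp20()), flat, tolerance = 1e-10)
})

test_that("retrieval inverts the TIE forward model exactly on any shape", {
  prm <- pp20(gamma = 200, z_mm = 200)
  for (n in c(64L, 100L, 96L)) {
    img <- exp(-phantom_image(default_phantom(n)))
    fw <- tie_forward(img, prm, crop = FALSE)
    back <- phase_retrieve(fw, prm)[seq_len(n), seq_len(n)]
    expect_lt(max(abs(back - img)) / max(abs(img)), 1e-6)
  }
})

test_that("phase retrieval strictly reduces high-frequency energy", {
  hf_energy <- function(m) {
    FT <- stats::fft(m - mean(m))
    fy <- ctpipe:::fft_freqs(nrow(m)); fx <- ctpipe:::fft_freqs(ncol(m))
    hf <- outer(abs(fy) > 0.125, abs(fx) > 0.125, "|")
    sum(Mod(FT[hf])^2)
  }
  set.seed(8)
  for (rep in 1:5) {
    img <- matrix(runif(64 * 64), 64, 64)
    out <- phase_retrieve(img, pp20(gamma = 50, z_mm = 50))
    expect_lt(hf_energy(out), hf_energy(img))
  }
})

test_that("contrast-to-noise of a low-contrast pair improves after retrieval", {
  prm <- pp20(gamma = 200, z_mm = 200)
  pair <- phantom_spec(data.frame(x0 = c(-0.3, 0.3), y0 = 0, a = 0.25,
                                  b = 0.25, phi_deg = 0,
                                  mu = c(0.010, 0.0104)),
                       grid = c(128, 128))
  ang <- angle_grid(203)
  I <- exp(-analytic_sinogram(pair, ang, 128)$values)
  set.seed(9)
  fringed <- t(sapply(seq_along(ang), function(k)
    tie_forward(matrix(I[k, ], 8, 128, byrow = TRUE), prm)[4, ]))
  raw <- fringed + matrix(rnorm(length(fringed), 0, 0.002), nrow(fringed))
  retrieved <- t(sapply(seq_along(ang), function(k)
    phase_retrieve(matrix(raw[k, ], 8, 128, byrow = TRUE), prm)[4, ]))

  cnr <- function(vals) {
    sl <- fbp_slice(sinogram(negative_log(vals), ang))
    ctr <- function(cols) mean(sl[58:70, cols])
    abs(ctr(93:108) - ctr(20:35)) / sd(sl[10:20, 10:20])
  }
  expect_gt(cnr(retrieved), cnr(raw))
})

test_that("beam-hardening correction applies the declared polynomial", {
  p <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(beam_hardening_correct(p, bh_params(0)), p)
  expect_equal(beam_hardening_correct(2, bh_params(0.05)), 2.2)
  # monotone increasing for c2 >= 0 on x >= 0
  x <- seq(0, 5, by = 0.01)
  y <- beam_hardening_correct(x, bh_params(0.3))
  expect_true(all(diff(y) > 0))
  # intensity domain does not clamp negatives away from the declared domain
  expect_equal(beam_hardening_correct(-0.5, bh_params(0.1, "intensity")),
               -0.5 + 0.1 * 0.25)
})

test_that("a positive c2 minimises cupping on simulated polychromatic data", {
  ang <- angle_grid(203)
  disc <- disc_phantom(grid = 128L, radius = 0.6, mu = 0.02)
  g <- scan_geometry(n_projections = 203, angles_deg = ang,
                     detector_rows = 2, detector_cols = 128)
  acq <- simulate_acquisition(
    disc, g,
    artefact_model(hardening = list(w1 = 0.6, scale1 = 1.6,
                                    w2 = 0.4, scale2 = 0.55)),
    n_flats = 4, n_darks = 4)
  p <- negative_log(flat_dark_correct(acq$projections,
                                      reference_images(acq$darks, acq$flats)))
  cupping <- function(c2) {
    pc <- beam_hardening_correct(p, bh_params(c2))
    sl <- fbp_slice(sinogram(t(pc[1, , ]), ang))
    mean(sl[60:69, 60:69]) - mean(sl[64, c(28:33, 96:101)])
  }
  expect_lt(cupping(0), 0)                       # cupped before correction
  c2s <- seq(0, 0.6, by = 0.05)
  best <- c2s[which.min(abs(vapply(c2s, cupping, numeric(1))))]
  expect_gt(best, 0)
})
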