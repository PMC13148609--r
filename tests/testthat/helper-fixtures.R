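# Shared fixture builders. Everything is generated in code at test time.

# uniform half-open angle grid over [0, range) degrees
angle_grid <- function(n, range = 180) seq(0, range, length.out = n + 1L)[seq_len(n)]

# a centred uniform disc phantom
disc_phantom <- function(grid = 128L, radius = 0.5, mu = 1) {
  phantom_spec(data.frame(x0 = 0, y0 = 0, a = radius, b = radius,
                          phi_deg = 0, mu = mu),
               grid = c(grid, grid))
}

# noise-free simulated scan of the default phantom (extruded), few rows
sim_scan <- function(grid = 64L, n_proj = NULL, rows = 4L,
                     artefacts = artefact_model(), angles_deg = NULL, ...) {
  if (is.null(n_proj)) n_proj <- min_projection_count(grid)
  if (is.null(angles_deg)) angles_deg <- angle_grid(n_proj)
  g <- scan_geometry(n_projections = n_proj, angles_deg = angles_deg,
                     detector_rows = rows, detector_cols = grid, ...)
  simulate_acquisition(default_phantom(grid), g, artefacts,
                       n_flats = 4L, n_darks = 4L)
}

# line-integral projection stack of a phantom, extruded over `rows`
lineint_stack <- function(phantom, angles, n_cols, rows) {
  s <- analytic_sinogram(phantom, angles, n_cols)
  proj <- array(0, c(rows, n_cols, length(angles)))
  for (k in seq_along(angles))
    proj[, , k] <- matrix(s$values[k, ], rows, n_cols, byrow = TRUE)
  proj
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# brute-force numerical line integral through an ellipse phantom,
# independent of the closed-form chord path (dense sampling oracle)
brute_line_integral <- function(phantom, theta_deg, t_units, ds = 5e-5) {
  th <- theta_deg * pi / 180
  s <- seq(-1.5, 1.5, by = ds)
  x <- t_units * cos(th) - s * sin(th)
  y <- t_units * sin(th) + s * cos(th)
  total <- 0
  for (i in seq_len(nrow(phantom$shapes))) {
    sh <- phantom$shapes[i, ]
    phi <- sh$phi_deg * pi / 180
    xr <- (x - sh$x0) * cos(phi) + (y - sh$y0) * sin(phi)
    yr <- -(x - sh$x0) * sin(phi) + (y - sh$y0) * cos(phi)
    total <- total + sh$mu * sum((xr / sh$a)^2 + (yr / sh$b)^2 <= 1) * ds
  }
  total
}
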