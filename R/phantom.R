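#' Analytic ellipse phantom specification
#'
#' A phantom is a list of ellipses, each with a centre, semi-axes, rotation
#' and an additive attenuation per unit length, on a square grid whose
#' physical extent maps the grid width onto the detector width. Overlapping
#' ellipses add, so nested structures are built by stacking positive and
#' negative attenuations (as in the classic head phantom).
#'
#' Coordinates are in units of the half-width of the field of view
#' (the reconstruction circle has radius 1).
#'
#' @param shapes Data frame (or list of lists) with columns `x0`, `y0`
#'   (centre), `a`, `b` (semi-axes), `phi_deg` (rotation) and `mu`
#'   (attenuation per pixel traversed at unit chord).
#' @param grid Integer `(width, height)` of the rasterised phantom.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shapes, grid = c(256L, 256L)) {
  shapes <- as.data.frame(shapes)
  need <- c("x0", "y0", "a", "b", "phi_deg", "mu")
  stopifnot(all(need %in% names(shapes)), all(is.finite(shapes$mu)),
            all(shapes$a > 0), all(shapes$b > 0))
  structure(list(shapes = shapes, grid = as.integer(grid)),
            class = "phantom_spec")
}

#' Built-in multi-ellipse phantom
#'
#' A head-phantom-style layout: an outer shell, an interior disc, two
#' off-centre cavities, a small dense inclusion, plus a low-contrast
#' two-density pair (1.00 vs 1.04 relative attenuation) for exercising
#' phase-retrieval contrast enhancement.
#'
#' @param grid Raster size (square).
#' @param mu_scale Attenuation scale applied to all shapes. The default
#'   `4 / grid` keeps the maximum line integral near 2 regardless of raster
#'   size, i.e. a minimum transmission around 15% — a realistic mid-density
#'   specimen that stays well inside the 16-bit detector range.
#' @return A [phantom_spec()].
#' @export
default_phantom <- function(grid = 256L, mu_scale = 4 / grid) {
  # deliberately asymmetric layout: mirror-symmetric phantoms degrade the
  # correlation-based COR search (the mirrored projection then resembles the
  # unmirrored one at zero shift)
  shapes <- data.frame(
    x0 = c(0.02, 0.02, 0.38, -0.26, 0.08, 0.45, 0.22),
    y0 = c(0, 0, 0.28, 0.34, -0.44, -0.30, -0.38),
    a = c(0.88, 0.82, 0.16, 0.26, 0.22, 0.08, 0.12),
    b = c(0.78, 0.72, 0.30, 0.14, 0.12, 0.08, 0.12),
    phi_deg = c(0, 0, -25, 40, 10, 0, 0),
    mu = mu_scale * c(1.0, -0.5, -0.25, -0.30, 0.35, 0.55, 0.45)
  )
  phantom_spec(shapes, grid = c(grid, grid))
}

#' Rasterise a phantom onto its grid
#'
#' Ground-truth image for reconstruction-error metrics: each pixel receives
#' the sum of the attenuations of the ellipses containing its centre.
#' Values are attenuation per pixel, matching what [fbp_slice()] of the
#' [analytic_sinogram()] reconstructs.
#'
#' @param phantom A [phantom_spec()].
#' @param supersample Sub-pixel sampling factor per axis for anti-aliased
#'   edges (1 = pixel-centre membership test).
#' @return `[height, width]` matrix.
#' @export
phantom_image <- function(phantom, supersample = 2L) {
  if (supersample > 1L) {
    up <- phantom
    up$grid <- phantom$grid * as.integer(supersample)
    big <- phantom_image(up, supersample = 1L)
    h <- phantom$grid[2]; w <- phantom$grid[1]; s <- as.integer(supersample)
    # box-average s x s blocks
    out <- matrix(0, h, w)
    for (dy in seq_len(s)) for (dx in seq_len(s))
      out <- out + big[seq(dy, by = s, length.out = h),
                       seq(dx, by = s, length.out = w)]
    return(out / s^2)
  }
  w <- phantom$grid[1]; h <- phantom$grid[2]
  # pixel centres in units of the half-width; radius of the grid = 1
  x <- ((seq_len(w) - 1) - (w - 1) / 2) / (w / 2)
  y <- ((seq_len(h) - 1) - (h - 1) / 2) / (h / 2)
  xs <- matrix(x, h, w, byrow = TRUE)
  ys <- matrix(y, h, w)
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(phantom$shapes))) {
    s <- phantom$shapes[i, ]
    phi <- s$phi_deg * pi / 180
    xr <- (xs - s$x0) * cos(phi) + (ys - s$y0) * sin(phi)
    yr <- -(xs - s$x0) * sin(phi) + (ys - s$y0) * cos(phi)
    img <- img + s$mu * ((xr / s$a)^2 + (yr / s$b)^2 <= 1)
  }
  img
}

#' Analytic parallel-beam sinogram of an ellipse phantom
#'
#' Exact Radon transform: the line integral of a uniform ellipse along a ray
#' at angle `theta` and signed axis distance `t` is the chord length
#' `2 mu a b sqrt(s^2 - tau^2) / s^2` with
#' `s^2 = a^2 cos^2(theta - phi) + b^2 sin^2(theta - phi)` and `tau` the
#' distance of the ray from the ellipse centre; integrals are additive over
#' shapes. Attenuations are scaled so that values are per *pixel* of path,
#' i.e. a centred disc of radius `r` (units of half-width) and `mu` gives a
#' central ray value `2 r (n_cols / 2) mu`.
#'
#' @param phantom A [phantom_spec()].
#' @param angles_deg Projection angles in degrees.
#' @param n_cols Detector width in pixels.
#' @param cor_offset_px Signed rotation-axis offset from the detector centre
#'   column (the sinogram is shifted accordingly).
#' @return A [sinogram()].
#' @export
analytic_sinogram <- function(phantom, angles_deg, n_cols,
                              cor_offset_px = 0) {
  half_px <- n_cols / 2
  # detector coordinate of each column relative to the rotation axis,
  # in units of the phantom half-width
  det_centre <- (n_cols - 1) / 2
  t_units <- ((seq_len(n_cols) - 1) - det_centre - cor_offset_px) / half_px
  th <- angles_deg * pi / 180
  v <- matrix(0, length(th), n_cols)
  for (i in seq_len(nrow(phantom$shapes))) {
    s <- phantom$shapes[i, ]
    phi <- s$phi_deg * pi / 180
    ct <- cos(th - phi); st <- sin(th - phi)
    s2 <- s$a^2 * ct^2 + s$b^2 * st^2                   # per angle
    # ray offset from ellipse centre: tau = t - (x0 cos th + y0 sin th)
    proj_centre <- s$x0 * cos(th) + s$y0 * sin(th)
    tau <- outer(-proj_centre, t_units, "+")            # [angles, cols]
    inside <- tau^2 < s2
    chord <- matrix(0, length(th), n_cols)
    chord[inside] <- (2 * s$mu * s$a * s$b *
                        sqrt(pmax(s2[row(tau)[inside]] - tau[inside]^2, 0)) /
                        s2[row(tau)[inside]])
    v <- v + chord
  }
  sinogram(v * half_px, angles_deg)
}

#' Detector artefact and noise model for simulated acquisitions
#'
#' @param flat_profile Function `(rows, cols) -> matrix` of the smooth
#'   multiplicative beam profile in detector counts (default: a separable
#'   cosine roll-off peaking at 30000 counts), or a pre-built matrix.
#' @param dark_offset_mean,dark_noise_sd Dark-field offset counts and
#'   Gaussian read-noise standard deviation.
#' @param poisson_scale Photons per unit of flat intensity; `Inf` disables
#'   photon noise.
#' @param bad_pixel_fraction Fraction of detector pixels planted as dead
#'   (zero flat response) or hot (saturated dark level).
#' @param stripe_defects List of `list(column =, gain =)` entries; `column`
#'   may be a vector for a wide stripe block. Gains multiply the flat
#'   response of those columns in the projections only (a miscalibration
#'   between references and scan), creating sinogram stripes.
#' @param cor_offset_px Planted rotation-axis offset in pixels.
#' @param tie_forward A [phase_params()] to synthesise propagation fringes,
#'   or `NULL`.
#' @param hardening `NULL` for a monochromatic beam, or
#'   `list(w1 =, scale1 =, w2 =, scale2 =)` describing a two-component
#'   polychromatic spectrum (`w1 + w2 = 1`; the transmitted intensity is
#'   `w1 exp(-scale1 p) + w2 exp(-scale2 p)`).
#' @param seed Integer seed; recorded in the acquisition metadata.
#' @return An `artefact_model` object.
#' @export
artefact_model <- function(flat_profile = NULL,
                           dark_offset_mean = 100, dark_noise_sd = 0,
                           poisson_scale = Inf,
                           bad_pixel_fraction = 0,
                           stripe_defects = list(),
                           cor_offset_px = 0,
                           tie_forward = NULL,
                           hardening = NULL,
                           seed = 1L) {
  if (!is.null(hardening)) {
    stopifnot(abs(hardening$w1 + hardening$w2 - 1) < 1e-9,
              hardening$scale1 > 0, hardening$scale2 > 0)
  }
  for (sd_ in stripe_defects) stopifnot(sd_$gain > 0)
  structure(list(flat_profile = flat_profile,
                 dark_offset_mean = dark_offset_mean,
                 dark_noise_sd = dark_noise_sd,
                 poisson_scale = poisson_scale,
                 bad_pixel_fraction = bad_pixel_fraction,
                 stripe_defects = stripe_defects,
                 cor_offset_px = cor_offset_px,
                 tie_forward = tie_forward,
                 hardening = hardening,
                 seed = as.integer(seed)), class = "artefact_model")
}

default_flat_profile <- function(rows, cols, peak = 30000) {
  ry <- 0.75 + 0.25 * cos(pi * (seq_len(rows) - (rows + 1) / 2) / rows)
  rx <- 0.75 + 0.25 * cos(pi * (seq_len(cols) - (cols + 1) / 2) / cols)
  peak * outer(ry, rx)
}

#' Simulate a full acquisition
#'
#' Forward-models the beamline data products for an ellipse phantom:
#' analytic line integrals per detector row (the phantom is extruded along
#' the rotation axis), optional polychromatic hardening
#' (`sum_i w_i exp(-scale_i p)`), optional TIE propagation fringes, the
#' multiplicative flat profile, per-column gain stripes, Poisson photon
#' noise, dark offset with Gaussian read noise, planted bad pixels, and
#' final 16-bit quantisation. All planted ground-truth parameters (COR
#' offset, stripe columns, bad-pixel indices, seed) are stored in the
#' metadata for recovery tests.
#'
#' @param phantom A [phantom_spec()].
#' @param geometry A [scan_geometry()].
#' @param artefacts An [artefact_model()].
#' @param n_flats,n_darks Number of reference frames.
#' @return An `acquisition` object.
#' @export
simulate_acquisition <- function(phantom, geometry,
                                 artefacts = artefact_model(),
                                 n_flats = 8L, n_darks = 8L) {
  validate_geometry(geometry)
  set.seed(artefacts$seed)
  rows <- geometry$detector_rows; cols <- geometry$detector_cols
  n <- geometry$n_projections
  flat <- artefacts$flat_profile
  if (is.null(flat)) flat <- default_flat_profile(rows, cols)
  if (is.function(flat)) flat <- flat(rows, cols)
  stopifnot(all(dim(flat) == c(rows, cols)))

  sino <- analytic_sinogram(phantom, geometry$angles_deg, cols,
                            cor_offset_px = artefacts$cor_offset_px)
  p_row <- sino$values                                  # [n, cols]

  stripe_gain <- rep(1, cols)
  stripe_cols <- integer()
  for (sd_ in artefacts$stripe_defects) {
    stripe_gain[sd_$column] <- stripe_gain[sd_$column] * sd_$gain
    stripe_cols <- c(stripe_cols, sd_$column)
  }

  trans <- if (is.null(artefacts$hardening)) exp(-p_row) else {
    h <- artefacts$hardening
    h$w1 * exp(-h$scale1 * p_row) + h$w2 * exp(-h$scale2 * p_row)
  }

  proj <- array(0L, c(rows, cols, n))
  for (k in seq_len(n)) {
    # phantom extruded vertically: every detector row sees the same slice
    frame <- matrix(trans[k, ], rows, cols, byrow = TRUE)
    if (!is.null(artefacts$tie_forward))
      frame <- tie_forward(frame, artefacts$tie_forward)
    signal <- flat * frame * matrix(stripe_gain, rows, cols, byrow = TRUE)
    signal <- sample_counts(signal, artefacts)
    if (max(signal) > 65535)
      stop("simulated intensities exceed 16-bit range; lower poisson_scale ",
           "or the flat profile peak")
    proj[, , k] <- signal
  }

  flats <- array(0L, c(rows, cols, n_flats))
  for (k in seq_len(n_flats)) flats[, , k] <- sample_counts(flat, artefacts)
  darks <- array(0L, c(rows, cols, n_darks))
  for (k in seq_len(n_darks))
    darks[, , k] <- pmax(0L, round(artefacts$dark_offset_mean +
      stats::rnorm(rows * cols, 0, artefacts$dark_noise_sd)))

  bad_idx <- integer()
  if (artefacts$bad_pixel_fraction > 0) {
    n_bad <- max(1L, round(artefacts$bad_pixel_fraction * rows * cols))
    bad_idx <- sample.int(rows * cols, n_bad)
    dead <- bad_idx[seq_len(ceiling(n_bad / 2))]
    hot <- setdiff(bad_idx, dead)
    for (k in seq_len(n)) { f <- proj[, , k]; f[dead] <- 0L
      f[hot] <- 65535L; proj[, , k] <- f }
    for (k in seq_len(n_flats)) { f <- flats[, , k]; f[dead] <- 0L
      f[hot] <- 65535L; flats[, , k] <- f }
    for (k in seq_len(n_darks)) { f <- darks[, , k]
      f[hot] <- 65535L; darks[, , k] <- f }
  }

  geometry$cor_offset_px <- artefacts$cor_offset_px
  acquisition(proj, flats, darks, geometry,
              metadata = list(
                seed = artefacts$seed,
                true_cor_offset_px = artefacts$cor_offset_px,
                stripe_columns = if (length(stripe_cols)) stripe_cols else -1L,
                bad_pixel_index = if (length(bad_idx)) bad_idx else -1L))
}

# Quantise a noise-free count image, adding dark offset, Poisson photon
# noise (at poisson_scale photons per count unit) and read noise.
sample_counts <- function(signal, artefacts) {
  out <- signal
  if (is.finite(artefacts$poisson_scale)) {
    lam <- signal * artefacts$poisson_scale / max(signal)
    out <- stats::rpois(length(lam), lam) * max(signal) /
      artefacts$poisson_scale
    out <- matrix(out, nrow(signal), ncol(signal))
  }
  out <- out + artefacts$dark_offset_mean
  if (artefacts$dark_noise_sd > 0)
    out <- out + stats::rnorm(length(out), 0, artefacts$dark_noise_sd)
  matrix(pmax(0L, as.integer(round(out))), nrow(signal), ncol(signal))
}

#' Simulate a horizontally tiled acquisition
#'
#' Simulates the full wide field of view, then crops `n_h` overlapping
#' horizontal tiles with exact nominal offsets, aggregating everything into
#' one acquisition whose metadata records the tile offsets. A crop of tile
#' `t` spans columns `[(t-1) * step + 1, (t-1) * step + tile_cols]` of the
#' full field, `step = tile_cols - overlap_px`.
#'
#' @param phantom A [phantom_spec()].
#' @param geometry A [scan_geometry()] whose `detector_cols` is the *full*
#'   stitched width and whose `tiling$n_h` gives the tile count.
#' @param overlap_px Overlap between adjacent tiles, at least 8 px.
#' @param artefacts An [artefact_model()].
#' @return List with `tiles` (list of per-tile projection stacks),
#'   `offsets_px` (true integer x-offsets), `full` (the uncropped
#'   acquisition).
#' @export
make_tiled_acquisition <- function(phantom, geometry, overlap_px = 16L,
                                   artefacts = artefact_model()) {
  stopifnot(overlap_px >= 8L, !is.null(geometry$tiling))
  n_h <- geometry$tiling$n_h
  full_cols <- geometry$detector_cols
  tile_cols <- ceiling((full_cols + (n_h - 1L) * overlap_px) / n_h)
  step <- tile_cols - overlap_px
  if ((n_h - 1L) * step + tile_cols < full_cols)
    tile_cols <- full_cols - (n_h - 1L) * step
  if (tile_cols < overlap_px + 1L)
    stop("tiling exceeds the phantom field of view")
  full <- simulate_acquisition(phantom, geometry, artefacts)
  offsets <- as.integer((seq_len(n_h) - 1L) * step)
  tiles <- lapply(offsets, function(x0)
    full$projections[, (x0 + 1L):(x0 + tile_cols), , drop = FALSE])
  list(tiles = tiles, offsets_px = offsets, full = full)
}
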