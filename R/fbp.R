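#' Filtered back-projection of one sinogram
#'
#' Classical parallel-beam FBP: each sinogram row is zero-padded to at least
#' twice the next power of two of the column count, multiplied in the
#' frequency domain by the selected [build_filter()] response, inverse
#' transformed and back-projected with bilinear interpolation on a grid
#' centred on the rotation axis. With angles spanning 180 degrees the
#' result is scaled by `pi / n_angles` (trapezoid-style angle weights are
#' used when the angle grid is non-uniform), so a uniform disc of
#' attenuation `mu` per pixel reconstructs to value `mu`.
#'
#' The sinogram must already be COR-corrected: the rotation axis is assumed
#' at column `(n_cols - 1) / 2` (0-based).
#'
#' @param sino A [sinogram()].
#' @param spec A [filter_spec()] (default Ram-Lak).
#' @param output_width Side of the square output slice in pixels (default
#'   `n_cols`).
#' @return `output_width x output_width` slice matrix.
#' @export
fbp_slice <- function(sino, spec = filter_spec("ramlak"),
                      output_width = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  v <- sino$values
  n_angles <- nrow(v); nc <- ncol(v)
  if (n_angles < 2L) stop("need at least 2 projection angles")
  if (is.null(output_width)) output_width <- nc
  filtered <- filter_sinogram(v, spec)
  backproject(filtered, sino$angles_deg, output_width)
}

# Ramp-filter every sinogram row (angle) along the column axis.
filter_sinogram <- function(v, spec) {
  nc <- ncol(v)
  m <- max(64L, 2L * next_pow2(nc))
  resp <- build_filter(spec, m)
  padded <- matrix(0, m, nrow(v))           # columns = angles, for mvfft
  padded[seq_len(nc), ] <- t(v)
  ft <- stats::mvfft(padded) * resp
  filt <- Re(stats::mvfft(ft, inverse = TRUE)) / m
  t(filt[seq_len(nc), , drop = FALSE])
}

# Back-project filtered rows onto a 0-centred square grid with bilinear
# (here: linear along the detector) interpolation. Angle weights are
# trapezoid-style bin widths, collapsing to pi/n for a uniform 180-deg grid.
backproject <- function(filtered, angles_deg, output_width) {
  n_angles <- nrow(filtered); nc <- ncol(filtered)
  th <- angles_deg * pi / 180
  w <- angle_weights(th)
  centre <- (output_width - 1) / 2
  xy <- seq_len(output_width) - 1 - centre
  det_centre <- (nc - 1) / 2
  xs <- matrix(xy, output_width, output_width, byrow = TRUE)   # x per column
  ys <- matrix(xy, output_width, output_width)                 # y per row
  slice <- matrix(0, output_width, output_width)
  for (i in seq_len(n_angles)) {
    t_px <- xs * cos(th[i]) + ys * sin(th[i]) + det_centre + 1  # 1-based
    j0 <- floor(t_px)
    fr <- t_px - j0
    inside0 <- j0 >= 1L & j0 <= nc
    inside1 <- (j0 + 1) >= 1L & (j0 + 1) <= nc
    row <- filtered[i, ]
    v0 <- matrix(0, output_width, output_width)
    v1 <- v0
    v0[inside0] <- row[j0[inside0]]
    v1[inside1] <- row[j0[inside1] + 1L]
    slice <- slice + w[i] * (v0 * (1 - fr) + v1 * fr)
  }
  slice
}

angle_weights <- function(th_rad) {
  n <- length(th_rad)
  if (n == 1L) return(pi)
  d <- diff(th_rad)
  if (max(d) - min(d) < 1e-9) return(rep(mean(d), n))  # uniform grid
  c(d[1], (utils::head(d, -1) + d[-1]) / 2, d[n - 1L])
}

#' Circular reconstruction mask
#'
#' Sets all pixels outside a centred circle to zero. The mask diameter is
#' `ratio` times the slice width; the default 0.98 trims 2% of the width,
#' removing the noisy corona outside the fully sampled field of view.
#'
#' @param slice Square slice matrix (or `[h, w, n]` stack).
#' @param ratio Mask diameter as a fraction of the image width, in `(0, 1]`.
#' @return Masked slice/stack.
#' @export
circle_mask <- function(slice, ratio = 0.98) {
  stopifnot(ratio > 0, ratio <= 1)
  if (length(dim(slice)) == 3L) {
    for (k in seq_len(dim(slice)[3]))
      slice[, , k] <- circle_mask(slice[, , k], ratio)
    return(slice)
  }
  h <- nrow(slice); w <- ncol(slice)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  r2 <- (ratio * w / 2)^2
  yy <- (seq_len(h) - 1 - cy)^2
  xx <- (seq_len(w) - 1 - cx)^2
  slice[outer(yy, xx, "+") > r2] <- 0
  slice
}

#' FDK cone-beam reconstruction
#'
#' The Feldkamp-Davis-Kress algorithm for a circular trajectory with a
#' virtual detector through the rotation axis: cosine pre-weighting of each
#' projection, row-wise ramp filtering, then voxel-driven back-projection
#' with the distance weight `(R / (R - w))^2`, where `R` is the
#' source-to-axis distance in pixels and `w` the voxel coordinate towards
#' the source. With `source_sample_mm = Inf` all weights collapse to 1 and
#' the result equals stacked row-by-row [fbp_slice()] reconstruction.
#'
#' @param projections `[rows, cols, n]` stack of attenuation line integrals
#'   (already COR-corrected).
#' @param geometry A [scan_geometry()]; `source_sample_mm` may be `Inf`.
#' @param spec A [filter_spec()].
#' @param z_range Optional 1-based inclusive range `c(z0, z1)` of output
#'   slices (detector-row indices) to reconstruct; used by the streaming
#'   slab path.
#' @return A [recon_volume()] of shape `[cols, cols, length(z_range)]`.
#' @export
fdk_volume <- function(projections, geometry, spec = filter_spec("ramlak"),
                       z_range = NULL) {
  d <- dim(projections)
  stopifnot(length(d) == 3L, d[3] == geometry$n_projections)
  nr <- d[1]; nc <- d[2]; n_angles <- d[3]
  R_px <- if (is.infinite(geometry$source_sample_mm)) Inf
          else geometry$source_sample_mm * 1000 / geometry$pixel_size_um
  if (!is.infinite(R_px) && R_px <= nc / 2)
    stop("source_sample_mm places the source inside the reconstruction field")
  if (is.null(z_range)) z_range <- c(1L, nr)
  stopifnot(z_range[1] >= 1L, z_range[2] <= nr, z_range[1] <= z_range[2])

  th <- geometry$angles_deg * pi / 180
  w_ang <- angle_weights(th)
  det_cu <- (nc - 1) / 2
  det_cv <- (nr - 1) / 2

  # cosine pre-weight (1 for parallel beam) then row-wise ramp filter
  filt <- array(0, c(nr, nc, n_angles))
  if (is.infinite(R_px)) {
    for (k in seq_len(n_angles))
      filt[, , k] <- filter_sinogram(projections[, , k], spec)
  } else {
    u <- seq_len(nc) - 1 - det_cu
    v <- seq_len(nr) - 1 - det_cv
    cosw <- R_px / sqrt(R_px^2 + outer(v^2, u^2, "+"))
    for (k in seq_len(n_angles))
      filt[, , k] <- filter_sinogram(projections[, , k] * cosw, spec)
  }

  nz <- z_range[2] - z_range[1] + 1L
  vol <- array(0, c(nc, nc, nz))
  xy <- seq_len(nc) - 1 - det_cu
  xs <- matrix(xy, nc, nc, byrow = TRUE)
  ys <- matrix(xy, nc, nc)
  for (k in seq_len(n_angles)) {
    ct <- cos(th[k]); st <- sin(th[k])
    u_par <- xs * ct + ys * st                 # detector coordinate
    P <- filt[, , k]
    if (is.infinite(R_px)) {
      # parallel limit: each output slice reads exactly one detector row,
      # identically to fbp_slice on that row's sinogram
      u_px <- u_par + det_cu + 1
      j0 <- floor(u_px); fu <- u_px - j0
      in_u0 <- j0 >= 1L & j0 <= nc
      in_u1 <- (j0 + 1) >= 1L & (j0 + 1) <= nc
      for (zz in seq_len(nz)) {
        row <- P[z_range[1] + zz - 1L, ]
        v0 <- matrix(0, nc, nc); v1 <- v0
        v0[in_u0] <- row[j0[in_u0]]
        v1[in_u1] <- row[j0[in_u1] + 1L]
        vol[, , zz] <- vol[, , zz] + w_ang[k] * (v0 * (1 - fu) + v1 * fu)
      }
    } else {
      w_par <- -xs * st + ys * ct              # towards the source
      mag <- R_px / (R_px - w_par)
      dist_w <- mag^2
      u_px <- u_par * mag + det_cu + 1
      j0 <- floor(u_px); fu <- u_px - j0
      in_u0 <- j0 >= 1L & j0 <= nc
      in_u1 <- (j0 + 1) >= 1L & (j0 + 1) <= nc
      for (zz in seq_len(nz)) {
        z <- (z_range[1] + zz - 1L) - 1 - det_cv
        v_px <- z * mag + det_cv + 1
        i0 <- floor(v_px); fv <- v_px - i0
        in_v0 <- i0 >= 1L & i0 <= nr
        in_v1 <- (i0 + 1) >= 1L & (i0 + 1) <= nr
        acc <- matrix(0, nc, nc)
        ok00 <- in_u0 & in_v0; ok10 <- in_u0 & in_v1
        ok01 <- in_u1 & in_v0; ok11 <- in_u1 & in_v1
        acc[ok00] <- acc[ok00] + P[cbind(i0[ok00], j0[ok00])] *
          ((1 - fu) * (1 - fv) * dist_w)[ok00]
        acc[ok01] <- acc[ok01] + P[cbind(i0[ok01], j0[ok01] + 1L)] *
          (fu * (1 - fv) * dist_w)[ok01]
        acc[ok10] <- acc[ok10] + P[cbind(i0[ok10] + 1L, j0[ok10])] *
          ((1 - fu) * fv * dist_w)[ok10]
        acc[ok11] <- acc[ok11] + P[cbind(i0[ok11] + 1L, j0[ok11] + 1L)] *
          (fu * fv * dist_w)[ok11]
        vol[, , zz] <- vol[, , zz] + w_ang[k] * acc
      }
    }
  }
  recon_volume(vol, voxel_size_um = geometry$pixel_size_um,
               provenance = list(list(stage = "fdk",
                                      filter = spec$name,
                                      cutoff_frac = spec$cutoff_frac,
                                      source_sample_mm = geometry$source_sample_mm,
                                      z_range = z_range)))
}
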