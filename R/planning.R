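#' Size accounting for scans and reconstructed volumes
#'
#' Raw projections are 16-bit (2 bytes per pixel); reconstructed volumes are
#' 32-bit floating point (4 bytes per voxel). Sizes are reported in binary
#' units (GiB = 2^30 bytes, TiB = 2^40 bytes), which is the convention under
#' which a 2560 x 2560 x 2160 volume rounds to 53 "GB" and a
#' 2564 x 2564 x 18817 volume to 461 "GB".
#'
#' @param volume_dims Integer triple `(width, height, depth)` of the output
#'   volume in voxels.
#' @param proj_dims Optional integer triple `(n, rows, cols)` of the raw
#'   projection stack; adds raw-data accounting when given.
#' @return A `size_plan` list: `raw_bytes`, `volume_dims`, `volume_bytes`,
#'   `volume_gib`, `volume_gib_rounded`, `volume_tib`, `volume_tib_rounded`.
#' @examples
#' plan_sizes(c(2560, 2560, 2160))$volume_gib_rounded  # 53
#' @export
plan_sizes <- function(volume_dims, proj_dims = NULL) {
  stopifnot(length(volume_dims) == 3L, all(volume_dims >= 1))
  volume_bytes <- prod(as.numeric(volume_dims)) * 4
  raw_bytes <- if (is.null(proj_dims)) NA_real_ else {
    stopifnot(length(proj_dims) == 3L, all(proj_dims >= 1))
    prod(as.numeric(proj_dims)) * 2
  }
  gib <- volume_bytes / 2^30
  tib <- volume_bytes / 2^40
  structure(list(
    raw_bytes = raw_bytes,
    volume_dims = as.numeric(volume_dims),
    volume_bytes = volume_bytes,
    volume_gib = gib,
    volume_gib_rounded = round(gib),
    volume_tib = tib,
    volume_tib_rounded = round(tib)
  ), class = "size_plan")
}

#' @export
print.size_plan <- function(x, ...) {
  cat(sprintf("<size_plan> volume %g x %g x %g float32 = %s bytes (%.1f GiB ~ %d GB",
              x$volume_dims[1], x$volume_dims[2], x$volume_dims[3],
              format(x$volume_bytes, big.mark = ","), x$volume_gib,
              x$volume_gib_rounded))
  if (x$volume_tib >= 1)
    cat(sprintf(", %.2f TiB ~ %d TB", x$volume_tib, x$volume_tib_rounded))
  cat(")\n")
  if (!is.na(x$raw_bytes))
    cat(sprintf("  raw 16-bit input: %.1f GiB\n", x$raw_bytes / 2^30))
  invisible(x)
}

#' Minimum projection count for full angular sampling
#'
#' The Nyquist-style sampling rule for parallel-beam CT requires roughly
#' pi/2 times the projection width in projections over 180 degrees:
#' `ceiling(pi/2 * detector_cols)`.
#'
#' @param detector_cols Projection width in pixels (after any stitching).
#' @return Integer minimum number of projections.
#' @examples
#' min_projection_count(2560)  # 4022
#' @export
min_projection_count <- function(detector_cols) {
  stopifnot(detector_cols >= 1)
  as.integer(ceiling(pi / 2 * detector_cols))
}

#' Fermat spiral trajectory
#'
#' Point `k` (0-based) sits at radius `spiral_step * sqrt(k)` and polar angle
#' `k` golden angles (137.5077640500378 degrees). Used for stepping a speckle
#' or grid pattern through non-repeating positions.
#'
#' @param n_points Number of points.
#' @param spiral_step Radial scale per sqrt-index, in the motion-stage units.
#' @return A two-column matrix `(x, y)` with `n_points` rows.
#' @export
fermat_spiral_points <- function(n_points, spiral_step = 1) {
  stopifnot(n_points >= 1, spiral_step > 0)
  k <- seq_len(n_points) - 1
  golden_deg <- 137.5077640500378
  r <- spiral_step * sqrt(k)
  th <- k * golden_deg * pi / 180
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Grid trajectory
#'
#' Row-major grid of `n_h x n_v` positions with steps `step_h`, `step_v`;
#' `serpentine = TRUE` reverses the x direction on alternate rows (boustro-
#' phedon path, minimising stage travel).
#'
#' @param n_h,n_v Number of positions along x and y.
#' @param step_h,step_v Step sizes.
#' @param serpentine Reverse x-direction on odd rows.
#' @return A two-column matrix `(x, y)` with `n_h * n_v` rows, in visit order.
#' @export
grid_points <- function(n_h, n_v, step_h = 1, step_v = 1, serpentine = FALSE) {
  stopifnot(n_h >= 1, n_v >= 1)
  out <- matrix(0, n_h * n_v, 2, dimnames = list(NULL, c("x", "y")))
  k <- 1L
  for (j in seq_len(n_v)) {
    xs <- (seq_len(n_h) - 1) * step_h
    if (serpentine && j %% 2L == 0L) xs <- rev(xs)
    out[k:(k + n_h - 1L), 1] <- xs
    out[k:(k + n_h - 1L), 2] <- (j - 1) * step_v
    k <- k + n_h
  }
  out
}
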