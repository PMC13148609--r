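#' Average a stack of reference frames
#'
#' Builds the averaged dark or flat reference image (per-pixel arithmetic
#' mean in floating point).
#'
#' @param stack `[rows, cols, n]` array or a single matrix.
#' @return A `[rows, cols]` numeric matrix.
#' @export
average_frames <- function(stack) {
  if (is.matrix(stack)) return(matrix(as.numeric(stack), nrow(stack)))
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L) stop("empty or invalid stack")
  m <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) m <- m + stack[, , k]
  m / d[3]
}

#' Reference images for flat/dark correction
#'
#' @param darks,flats Stacks (or single frames) of dark- and flat-field
#'   images.
#' @return A `reference_images` list with `dark_mean` and `flat_mean`.
#'   Warns when more than 1% of pixels have `flat_mean <= dark_mean`
#'   (beam off, dead columns, or swapped inputs).
#' @export
reference_images <- function(darks, flats) {
  dark_mean <- average_frames(darks)
  flat_mean <- average_frames(flats)
  stopifnot(all(dim(dark_mean) == dim(flat_mean)))
  bad <- mean(flat_mean - dark_mean <= 0)
  if (bad > 0.01)
    warning(sprintf("flat_mean <= dark_mean on %.1f%% of pixels", 100 * bad))
  structure(list(dark_mean = dark_mean, flat_mean = flat_mean),
            class = "reference_images")
}

#' Dark- and flat-field correction
#'
#' The first operation of raw correction: normalise a raw intensity
#' projection `I` by the averaged references,
#' `I_cor = (I - dark_mean) / (flat_mean - dark_mean)`,
#' giving values near 1 where no sample is present. Denominators smaller
#' than `eps` are clamped to `eps` and counted.
#'
#' @param img Raw projection, matrix or `[rows, cols, n]` stack.
#' @param refs A [reference_images()] object.
#' @param eps Denominator clamp; default `1e-6` of the flat dynamic range.
#' @return Corrected image/stack with attribute `"n_clamped"`.
#' @export
flat_dark_correct <- function(img, refs, eps = NULL) {
  stopifnot(inherits(refs, "reference_images"))
  den <- refs$flat_mean - refs$dark_mean
  if (is.null(eps)) eps <- 1e-6 * max(abs(den), 1)
  stopifnot(eps > 0)
  n_clamped <- sum(den < eps)
  den <- pmax(den, eps)
  out <- if (length(dim(img)) == 3L) {
    a <- array(0, dim(img))
    for (k in seq_len(dim(img)[3]))
      a[, , k] <- (img[, , k] - refs$dark_mean) / den
    a
  } else {
    (img - refs$dark_mean) / den
  }
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Detect defective detector pixels from reference frames
#'
#' Flags pixels whose dark level or flat response is a robust outlier: the
#' deviation of `dark_mean` or `flat_mean` from its image median exceeds
#' `k` times the image MAD, or the flat response is not above the dark level
#' (dead pixel). Detection uses reference frames only, so it is unbiased by
#' the sample.
#'
#' @param darks,flats Reference stacks with at least 2 frames each.
#' @param k MAD multiplier (default 5).
#' @return Logical matrix, `TRUE` at defective pixels.
#' @export
detect_bad_pixels <- function(darks, flats, k = 5) {
  stopifnot(dim(darks)[3] >= 2L, dim(flats)[3] >= 2L)
  dm <- average_frames(darks)
  fm <- average_frames(flats)
  robust_out <- function(m) {
    med <- stats::median(m)
    s <- stats::mad(m)
    if (s == 0) s <- .Machine$double.eps
    abs(m - med) > k * s
  }
  mask <- robust_out(dm) | robust_out(fm) | (fm <= dm)
  if (all(mask)) stop("all pixels flagged as bad: inconsistent reference data")
  mask
}

#' Repair flagged pixels
#'
#' Replaces each flagged pixel by the median of its unflagged neighbours in
#' a 3x3 window, growing the window (with a warning) for pixels whose whole
#' neighbourhood is flagged. Unflagged pixels pass through unchanged.
#'
#' @param img Image matrix.
#' @param mask Logical matrix, `TRUE` where pixels must be repaired.
#' @return Repaired image.
#' @export
repair_pixels <- function(img, mask) {
  stopifnot(all(dim(img) == dim(mask)))
  if (!any(mask)) return(img)
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  idx <- which(mask, arr.ind = TRUE)
  for (t in seq_len(nrow(idx))) {
    i <- idx[t, 1]; j <- idx[t, 2]
    h <- 1L
    repeat {
      ri <- max(1L, i - h):min(nr, i + h)
      cj <- max(1L, j - h):min(nc, j + h)
      good <- !mask[ri, cj]
      if (any(good)) {
        out[i, j] <- stats::median(img[ri, cj][good])
        break
      }
      h <- h + 1L
      warning("expanding repair window at (", i, ",", j, ") to ", 2 * h + 1)
      if (h > max(nr, nc)) stop("no unflagged pixels available for repair")
    }
  }
  out
}

#' Threshold median filter
#'
#' Impulse-noise suppression: a pixel is replaced by its local window median
#' only where it deviates from that median by more than `threshold`;
#' everything else is untouched, so smooth structure is preserved and the
#' filter is idempotent for fixed parameters.
#'
#' @param img Image matrix.
#' @param threshold Positive intensity deviation triggering replacement.
#' @param window Odd window width (default 3).
#' @return Filtered image.
#' @export
threshold_median_filter <- function(img, threshold, window = 3L) {
  stopifnot(threshold > 0)
  med <- local_median(img, window)
  hit <- abs(img - med) > threshold
  img[hit] <- med[hit]
  img
}

#' Trim an acquisition
#'
#' Crops the projection images and/or subsamples the projection set.
#' Ranges are 1-based inclusive index vectors in R convention; the angle
#' vector is subsampled consistently with the projection stride.
#'
#' @param acq An `acquisition`.
#' @param rows,cols Index vectors of detector rows/columns to keep (default
#'   all).
#' @param projection_stride Keep every `stride`-th projection.
#' @return Trimmed `acquisition`.
#' @export
trim_acquisition <- function(acq, rows = NULL, cols = NULL,
                             projection_stride = 1L) {
  stopifnot(inherits(acq, "acquisition"), projection_stride >= 1L)
  d <- dim(acq$projections)
  if (is.null(rows)) rows <- seq_len(d[1])
  if (is.null(cols)) cols <- seq_len(d[2])
  if (any(rows < 1L | rows > d[1]) || any(cols < 1L | cols > d[2]))
    stop("trim ranges out of bounds")
  keep <- seq(1L, d[3], by = projection_stride)
  if (!length(rows) || !length(cols) || !length(keep))
    stop("trim would produce an empty dataset")
  g <- acq$geometry
  geometry <- scan_geometry(
    n_projections = length(keep), angles_deg = g$angles_deg[keep],
    detector_rows = length(rows), detector_cols = length(cols),
    pixel_size_um = g$pixel_size_um, energy_keV = g$energy_keV,
    propagation_distance_mm = g$propagation_distance_mm,
    source_sample_mm = g$source_sample_mm, cor_offset_px = g$cor_offset_px,
    tiling = g$tiling, angular_range_deg = g$angular_range_deg)
  acquisition(acq$projections[rows, cols, keep, drop = FALSE],
              acq$flats[rows, cols, , drop = FALSE],
              acq$darks[rows, cols, , drop = FALSE],
              geometry, acq$metadata)
}
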