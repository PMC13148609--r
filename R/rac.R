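#' Ring-artefact correction by stripe sorting
#'
#' Miscalibrated detector columns appear as vertical stripes in the sinogram
#' and as rings in the reconstructed slice. The sorting-based correction:
#' for every column, sort its values along the angle axis (remembering the
#' permutation), median-filter the sorted array across columns with an odd
#' window `filter_size`, then invert the permutation. Sorting makes the
#' angular profile of each column monotone, so a stripe becomes a smooth
#' offset between neighbouring columns that the cross-column median removes,
#' while genuine (smooth) sinogram structure is almost unchanged.
#'
#' Operates on the negative-log sinogram, where detector-gain stripes are
#' additive.
#'
#' @param sino A [sinogram()].
#' @param filter_size Odd median window across columns (default 9).
#' @return Corrected [sinogram()].
#' @export
rac_sort <- function(sino, filter_size = 9L) {
  stopifnot(inherits(sino, "sinogram"),
            filter_size %% 2L == 1L, filter_size >= 3L)
  v <- sino$values
  na <- nrow(v); nc <- ncol(v)
  ord <- apply(v, 2L, order)                  # per-column sort permutation
  sorted <- matrix(0, na, nc)
  for (j in seq_len(nc)) sorted[, j] <- v[ord[, j], j]
  # median across columns for each rank row, edge-replicated
  filtered <- t(apply(sorted, 1L, run_median, width = filter_size))
  out <- v
  for (j in seq_len(nc)) out[ord[, j], j] <- filtered[, j]
  sinogram(out, sino$angles_deg, sino$row_index)
}

#' Ring-artefact correction for large stripes
#'
#' Detects blocks of miscalibrated columns from the angular-mean profile of
#' the sinogram: the profile is smoothed with a wide running median and
#' columns whose deviation from the smooth profile exceeds
#' `snr_threshold` robust standard deviations are flagged. Flagged columns
#' are corrected by subtracting their offset from the smooth profile (gain
#' stripes are additive in the negative-log domain); all other columns are
#' returned bit-identical.
#'
#' @param sino A [sinogram()] (negative-log domain).
#' @param snr_threshold Detection threshold in robust sigma units
#'   (default 3).
#' @param filter_size Half the smoothing window is derived from this odd
#'   width; the running-median window is `2 * filter_size + 1` columns wide
#'   so that stripe blocks up to `filter_size` columns are detectable
#'   (default 21).
#' @return List with `sinogram` (corrected) and `mask` (logical, detected
#'   columns). Warns when more than half the columns are detected.
#' @export
rac_large <- function(sino, snr_threshold = 3, filter_size = 21L) {
  stopifnot(inherits(sino, "sinogram"), snr_threshold > 0)
  v <- sino$values
  profile <- colMeans(v)
  smooth <- run_median(profile, 2L * filter_size + 1L)
  dev <- profile - smooth
  # the noise scale is floored at 10% of the profile's own robust spread:
  # a large stripe must stand out from the residual smooth structure that
  # survives the running-median detrend, not merely from pixel noise
  sigma <- max(stats::mad(dev), 0.1 * stats::mad(profile))
  if (sigma == 0) sigma <- .Machine$double.eps
  mask <- abs(dev) > snr_threshold * sigma
  if (mean(mask) > 0.5)
    warning("more than 50% of columns detected as stripes; ",
            "snr_threshold is likely mis-set")
  out <- v
  if (any(mask))
    out[, mask] <- sweep(v[, mask, drop = FALSE], 2L, dev[mask], "-")
  list(sinogram = sinogram(out, sino$angles_deg, sino$row_index),
       mask = mask)
}

#' Apply the enabled ring-artefact corrections sequentially
#'
#' When both methods are enabled they run in sequence — stripe sorting
#' first (equalising small stripes stabilises large-stripe detection), then
#' large-stripe removal.
#'
#' @param sino A [sinogram()].
#' @param sort_enabled,large_enabled Stage toggles.
#' @param sort_filter_size,large_snr,large_filter_size Method parameters.
#' @return Corrected [sinogram()].
#' @export
rac_apply <- function(sino, sort_enabled = TRUE, large_enabled = TRUE,
                      sort_filter_size = 9L, large_snr = 3,
                      large_filter_size = 21L) {
  if (sort_enabled) sino <- rac_sort(sino, sort_filter_size)
  if (large_enabled)
    sino <- rac_large(sino, large_snr, large_filter_size)$sinogram
  sino
}
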