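#' Tile layout for stitching
#'
#' @param tiles List of image matrices (one projection angle at a time), or
#'   of `[rows, cols, n]` stacks sharing `n`.
#' @param offsets_px Two-column matrix of nominal `(x, y)` offsets in pixels
#'   of each tile's origin relative to the mosaic origin (0-based, x right,
#'   y down).
#' @return A `tile_layout` object.
#' @export
tile_layout <- function(tiles, offsets_px) {
  offsets_px <- matrix(as.numeric(offsets_px), ncol = 2)
  stopifnot(length(tiles) == nrow(offsets_px), length(tiles) >= 1L)
  if (nrow(unique(round(offsets_px))) < nrow(offsets_px))
    stop("tiles with identical offsets")
  structure(list(tiles = tiles, offsets_px = offsets_px),
            class = "tile_layout")
}

#' Convert motor positions in millimetres to detector pixel offsets
#'
#' @param mm Motor travel in millimetres.
#' @param pixel_size_um Detector pixel pitch in micrometres.
#' @return Offset in pixels (`mm * 1000 / pixel_size_um`).
#' @export
motor_mm_to_px <- function(mm, pixel_size_um) mm * 1000 / pixel_size_um

# Paste tiles at integer offsets with a linear ramp blend across overlaps.
# Accumulates weighted intensities and weights; the per-tile weight ramps
# from the tile border inward (separable distance-to-edge ramp, capped),
# which resolves overlaps smoothly and leaves single-coverage regions exact.
paste_tiles <- function(tiles, offsets, blend_margin = NULL) {
  offsets <- round(offsets)
  xs <- offsets[, 1]; ys <- offsets[, 2]
  ws <- vapply(tiles, ncol, integer(1)); hs <- vapply(tiles, nrow, integer(1))
  W <- max(xs + ws); H <- max(ys + hs)
  if (min(xs) < 0 || min(ys) < 0) {
    xs <- xs - min(c(xs, 0)); ys <- ys - min(c(ys, 0))
    W <- max(xs + ws); H <- max(ys + hs)
  }
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  for (t in seq_along(tiles)) {
    tl <- tiles[[t]]
    margin <- if (is.null(blend_margin))
      max(1L, min(nrow(tl), ncol(tl)) %/% 4L) else blend_margin
    ramp <- function(n) pmin(pmin(seq_len(n), rev(seq_len(n))) / margin, 1)
    w <- outer(ramp(nrow(tl)), ramp(ncol(tl)))
    ri <- ys[t] + seq_len(nrow(tl)); ci <- xs[t] + seq_len(ncol(tl))
    acc[ri, ci] <- acc[ri, ci] + tl * w
    wacc[ri, ci] <- wacc[ri, ci] + w
  }
  acc / pmax(wacc, .Machine$double.eps)
}

#' Stitch tiles by dead reckoning
#'
#' Pastes tiles at their nominal (motor-derived) offsets, rounded to integer
#' pixels, resolving overlaps with a linear ramp blend. Effective at low
#' magnification where motor positions are accurate on the detector scale.
#'
#' @param layout A [tile_layout()] whose offsets are already in pixels (use
#'   [motor_mm_to_px()] for motor positions in mm).
#' @return The mosaic image.
#' @export
stitch_dead_reckoning <- function(layout) {
  stopifnot(inherits(layout, "tile_layout"))
  if (length(layout$tiles) == 1L) return(layout$tiles[[1]])
  paste_tiles(layout$tiles, layout$offsets_px)
}

#' Stitch tiles by phase-correlation refinement
#'
#' Refines each tile's nominal offset by Fourier phase correlation of the
#' nominal overlap region with the mosaic assembled so far, constrained to
#' `search_radius_px` of the nominal value and rounded to integer pixels
#' (translation-only montage registration). Tiles whose correlation peak
#' falls below `confidence_floor` fall back to dead reckoning with a
#' warning. The first tile anchors the mosaic, so refined offsets are
#' globally consistent.
#'
#' @param layout A [tile_layout()] with nominal pixel offsets.
#' @param search_radius_px Maximum allowed correction of a nominal offset.
#' @param confidence_floor Minimum peak-to-second-peak ratio to accept a
#'   correlation result.
#' @return List with `offsets_px` (refined, integer) and `mosaic`.
#' @export
stitch_correlation <- function(layout, search_radius_px = 10,
                               confidence_floor = 2) {
  stopifnot(inherits(layout, "tile_layout"))
  tiles <- layout$tiles
  nominal <- round(layout$offsets_px)
  n <- length(tiles)
  refined <- nominal
  refined[1, ] <- nominal[1, ]
  for (t in seq_len(n)[-1]) {
    best <- NULL
    # register against the closest previously refined tile with overlap
    for (s in seq_len(t - 1L)) {
      ov <- overlap_region(refined[s, ], dim(tiles[[s]]),
                           nominal[t, ], dim(tiles[[t]]))
      if (is.null(ov)) next
      if (is.null(best) || ov$area > best$area) { best <- ov; best$s <- s }
    }
    if (is.null(best)) {
      warning("tile ", t, " has no overlap with previous tiles; dead reckoning")
      next
    }
    s <- best$s
    a <- tiles[[s]][best$ra_s, best$ca_s, drop = FALSE]
    b <- tiles[[t]][best$ra_t, best$ca_t, drop = FALSE]
    if (min(dim(a)) < 8L) {
      warning("overlap of tile ", t, " thinner than 8 px; dead reckoning")
      next
    }
    pc <- phase_correlate(a, b)
    corr <- c(round(pc$dx), round(pc$dy))       # (x, y) correction
    if (pc$confidence < confidence_floor) {
      warning("tile ", t, ": correlation confidence ",
              sprintf("%.2f", pc$confidence), " below floor; dead reckoning")
      next
    }
    if (any(abs(corr) > search_radius_px)) {
      warning("tile ", t, ": correlation shift outside search radius; ",
              "dead reckoning")
      next
    }
    refined[t, ] <- nominal[t, ] + corr
  }
  list(offsets_px = refined, mosaic = paste_tiles(tiles, refined))
}

# Overlap of two axis-aligned tiles given (x, y) offsets and dim() shapes.
# Returns index ranges into each tile plus the overlap area, or NULL.
overlap_region <- function(off_a, dim_a, off_b, dim_b) {
  ax0 <- off_a[1]; ay0 <- off_a[2]
  bx0 <- off_b[1]; by0 <- off_b[2]
  x0 <- max(ax0, bx0); x1 <- min(ax0 + dim_a[2], bx0 + dim_b[2])
  y0 <- max(ay0, by0); y1 <- min(ay0 + dim_a[1], by0 + dim_b[1])
  if (x1 - x0 < 1 || y1 - y0 < 1) return(NULL)
  list(
    ra_s = (y0 - ay0 + 1):(y1 - ay0), ca_s = (x0 - ax0 + 1):(x1 - ax0),
    ra_t = (y0 - by0 + 1):(y1 - by0), ca_t = (x0 - bx0 + 1):(x1 - bx0),
    area = (x1 - x0) * (y1 - y0))
}
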