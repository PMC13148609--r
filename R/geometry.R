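#' Scan geometry description
#'
#' Collects everything the pipeline needs to know about how an acquisition
#' was (or is to be) performed: the rotation angle grid, detector shape and
#' pixel pitch, beam energy, sample-to-detector propagation distance, the
#' source-to-sample distance (use `Inf` for the parallel-beam limit of a
#' synchrotron geometry), the signed centre-of-rotation offset and an
#' optional tiling layout for samples larger than the field of view.
#'
#' @param n_projections Number of projection images.
#' @param angles_deg Rotation angles in degrees, strictly increasing, one per
#'   projection. Default: uniform grid over `[0, angular_range_deg)`.
#' @param detector_rows,detector_cols Detector shape in pixels.
#' @param pixel_size_um Detector pixel pitch in micrometres.
#' @param energy_keV X-ray energy in keV.
#' @param propagation_distance_mm Sample-to-detector distance in millimetres
#'   (the free-space propagation distance used by phase retrieval).
#' @param source_sample_mm Source-to-sample distance in millimetres, or `Inf`
#'   for a parallel beam.
#' @param cor_offset_px Signed centre-of-rotation offset in pixels: the
#'   rotation-axis column minus the detector centre column `(cols - 1) / 2`.
#'   Positive means the axis sits right of centre.
#' @param tiling Either `NULL` (single field of view) or a list with elements
#'   `n_h`, `n_v` (tile counts) and `step_h_px`, `step_v_px` (motor step in
#'   pixels between adjacent tiles).
#' @param angular_range_deg Total angular range of the scan in degrees
#'   (180 for a standard parallel/slight-cone scan).
#'
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_projections,
                          angles_deg = NULL,
                          detector_rows,
                          detector_cols,
                          pixel_size_um = 6.5,
                          energy_keV = 20,
                          propagation_distance_mm = 0,
                          source_sample_mm = Inf,
                          cor_offset_px = 0,
                          tiling = NULL,
                          angular_range_deg = 180) {
  if (is.null(angles_deg)) {
    angles_deg <- seq(0, angular_range_deg, length.out = n_projections + 1L)[
      seq_len(n_projections)]
  }
  g <- structure(list(
    n_projections = as.integer(n_projections),
    angles_deg = as.numeric(angles_deg),
    detector_rows = as.integer(detector_rows),
    detector_cols = as.integer(detector_cols),
    pixel_size_um = pixel_size_um,
    energy_keV = energy_keV,
    propagation_distance_mm = propagation_distance_mm,
    source_sample_mm = source_sample_mm,
    cor_offset_px = cor_offset_px,
    tiling = tiling,
    angular_range_deg = angular_range_deg
  ), class = "scan_geometry")
  validate_geometry(g)
  g
}

#' Validate a scan geometry
#'
#' Checks the structural invariants of a [scan_geometry()]: at least one
#' projection, positive pixel size and energy, strictly increasing angles and
#' an angle vector whose length matches the projection count.
#'
#' @param g A `scan_geometry`.
#' @return `g`, invisibly; stops with a message on the first violated
#'   invariant.
#' @export
validate_geometry <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  if (g$n_projections < 1L) stop("geometry: n_projections must be >= 1")
  if (length(g$angles_deg) != g$n_projections)
    stop("geometry: length(angles_deg) != n_projections")
  if (g$n_projections > 1L && any(diff(g$angles_deg) <= 0))
    stop("geometry: angles_deg must be strictly increasing")
  if (g$pixel_size_um <= 0) stop("geometry: pixel_size_um must be > 0")
  if (g$energy_keV <= 0) stop("geometry: energy_keV must be > 0")
  if (g$detector_rows < 1L || g$detector_cols < 1L)
    stop("geometry: detector shape must be >= 1 in both axes")
  if (g$propagation_distance_mm < 0)
    stop("geometry: propagation_distance_mm must be >= 0")
  if (!is.infinite(g$source_sample_mm) && g$source_sample_mm <= 0)
    stop("geometry: source_sample_mm must be > 0 or Inf")
  if (!is.null(g$tiling)) {
    tl <- g$tiling
    need <- c("n_h", "n_v", "step_h_px", "step_v_px")
    if (!all(need %in% names(tl)))
      stop("geometry: tiling needs fields ", paste(need, collapse = ", "))
    if (tl$n_h < 1L || tl$n_v < 1L) stop("geometry: tile counts must be >= 1")
  }
  invisible(g)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry>\n")
  cat(sprintf("  projections : %d over [%g, %g] deg (range %g)\n",
              x$n_projections, min(x$angles_deg), max(x$angles_deg),
              x$angular_range_deg))
  cat(sprintf("  detector    : %d x %d px @ %g um\n",
              x$detector_rows, x$detector_cols, x$pixel_size_um))
  cat(sprintf("  beam        : %g keV, z = %g mm, source = %s mm\n",
              x$energy_keV, x$propagation_distance_mm,
              format(x$source_sample_mm)))
  cat(sprintf("  COR offset  : %g px\n", x$cor_offset_px))
  if (!is.null(x$tiling))
    cat(sprintf("  tiling      : %d x %d, step (%g, %g) px\n",
                x$tiling$n_h, x$tiling$n_v,
                x$tiling$step_h_px, x$tiling$step_v_px))
  invisible(x)
}

#' X-ray wavelength from photon energy
#'
#' `lambda = 1.239842e-9 / E[keV]` metres (the hc/E conversion with hc in
#' keV nm).
#'
#' @param energy_keV Photon energy in keV.
#' @return Wavelength in metres.
#' @export
xray_wavelength_m <- function(energy_keV) {
  stopifnot(energy_keV > 0)
  1.239842e-9 / energy_keV
}

#' Parameters for single-distance TIE-Hom phase retrieval
#'
#' The homogeneous-object (single delta/beta) transport-of-intensity filter
#' needs only the propagation distance `z`, the ratio `gamma = delta/beta`
#' of the refractive-index decrement to the absorption index, and the X-ray
#' wavelength (from the energy). `pad_mode` controls how images are extended
#' to the power-of-two FFT grid.
#'
#' @param gamma Ratio delta/beta, dimensionless, `>= 0`.
#' @param z_mm Propagation (sample-to-detector) distance in millimetres.
#' @param energy_keV X-ray energy in keV.
#' @param pixel_size_um Detector pixel pitch in micrometres.
#' @param pad_mode `"edge"` (replicate border values) or `"reflect"`.
#' @return An object of class `phase_params`.
#' @export
phase_params <- function(gamma, z_mm, energy_keV, pixel_size_um,
                         pad_mode = c("edge", "reflect")) {
  pad_mode <- match.arg(pad_mode)
  stopifnot(gamma >= 0, z_mm >= 0, energy_keV > 0, pixel_size_um > 0)
  structure(list(gamma = gamma, z_mm = z_mm, energy_keV = energy_keV,
                 pixel_size_um = pixel_size_um, pad_mode = pad_mode),
            class = "phase_params")
}

#' Parameters for polynomial beam-hardening correction
#'
#' A second-order linearisation `f(x) = x + c2 * x^2` applied either to the
#' attenuation line integrals (`domain = "attenuation"`, the default and the
#' physically natural choice) or to the normalised intensities.
#'
#' @param c2 Second-order coefficient; 0 is the identity. Adjust iteratively
#'   until cupping in a reconstructed uniform region is minimised.
#' @param domain `"attenuation"` or `"intensity"`.
#' @return An object of class `bh_params`.
#' @export
bh_params <- function(c2 = 0, domain = c("attenuation", "intensity")) {
  domain <- match.arg(domain)
  stopifnot(is.finite(c2))
  structure(list(c2 = c2, domain = domain), class = "bh_params")
}
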