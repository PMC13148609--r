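#' Sinogram container
#'
#' One detector row across all projection angles: an `[n_angles, n_cols]`
#' matrix of attenuation line integrals plus its angle vector. The unit on
#' which ring-artefact correction and slice reconstruction operate.
#'
#' @param values `[n_angles, n_cols]` numeric matrix.
#' @param angles_deg Projection angles in degrees, length `n_angles`.
#' @param row_index Source detector row (1-based), for provenance.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, angles_deg, row_index = NA_integer_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(angles_deg), all(is.finite(values)))
  structure(list(values = values, angles_deg = as.numeric(angles_deg),
                 row_index = row_index), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d columns (row %s), range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), format(x$row_index),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Extract the sinogram of one detector row from a projection stack
#'
#' @param projections `[rows, cols, n]` stack of line-integral projections.
#' @param angles_deg Angle vector, length `n`.
#' @param row Detector row (1-based).
#' @return A [sinogram()].
#' @export
extract_sinogram <- function(projections, angles_deg, row) {
  stopifnot(row >= 1L, row <= dim(projections)[1])
  sinogram(t(projections[row, , ]), angles_deg, row_index = row)
}

#' Negative-log conversion to attenuation line integrals
#'
#' `p = -log(pmax(I_cor, eps))`, so transmission 1 maps to 0. Values clamped
#' at `eps` are counted in the `"n_clamped"` attribute.
#'
#' @param i_cor Corrected intensity (any array shape).
#' @param eps Positive clamp for non-positive intensities.
#' @return Line integrals, same shape, with attribute `"n_clamped"`.
#' @export
negative_log <- function(i_cor, eps = 1e-6) {
  stopifnot(eps > 0)
  n_clamped <- sum(i_cor < eps)
  out <- -log(pmax(i_cor, eps))
  attr(out, "n_clamped") <- n_clamped
  out
}
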