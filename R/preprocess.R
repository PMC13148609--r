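#' TIE-Hom frequency response
#'
#' The single-distance, homogeneous-object transport-of-intensity low-pass
#' filter (Paganin-type phase retrieval):
#' `H(u) = 1 / (1 + pi * lambda * z * gamma * |u|^2)`
#' with `u` the spatial frequency vector in cycles per metre on a grid with
#' pitch equal to the detector pixel size, `lambda` the X-ray wavelength,
#' `z` the propagation distance and `gamma = delta/beta`. `H(0) = 1` and
#' `0 < H <= 1` everywhere; `gamma = 0` or `z = 0` gives the identity.
#'
#' @param shape Integer `(rows, cols)` of the (padded) grid.
#' @param params A [phase_params()].
#' @return A `[rows, cols]` matrix of filter values laid out in FFT order.
#' @export
tie_hom_filter <- function(shape, params) {
  stopifnot(inherits(params, "phase_params"), length(shape) == 2L)
  lambda_m <- xray_wavelength_m(params$energy_keV)
  z_m <- params$z_mm * 1e-3
  px_m <- params$pixel_size_um * 1e-6
  fy <- fft_freqs(shape[1]) / px_m     # cycles per metre
  fx <- fft_freqs(shape[2]) / px_m
  u2 <- outer(fy^2, fx^2, "+")
  1 / (1 + pi * lambda_m * z_m * params$gamma * u2)
}

#' Single-distance TIE-Hom phase retrieval
#'
#' Suppresses propagation-induced phase-contrast fringes in a flat/dark-
#' corrected intensity projection: the image is padded on each axis to the
#' next power of two (edge replication by default), transformed with a 2-D
#' FFT, multiplied by the [tie_hom_filter()] response, inverse transformed
#' and cropped back. Since `H(0) = 1` the mean intensity is preserved; the
#' `-log` conversion to attenuation happens later, in reconstruction
#' ([negative_log()]).
#'
#' @param img Corrected intensity projection (matrix, background near 1) or
#'   a `[rows, cols, n]` stack.
#' @param params A [phase_params()].
#' @return Retrieved (fringe-suppressed) intensity, same shape as `img`.
#' @export
phase_retrieve <- function(img, params) {
  if (length(dim(img)) == 3L) {
    out <- array(0, dim(img))
    for (k in seq_len(dim(img)[3]))
      out[, , k] <- phase_retrieve(img[, , k], params)
    return(out)
  }
  if (!all(is.finite(img))) stop("non-finite values in phase retrieval input")
  r0 <- nrow(img); c0 <- ncol(img)
  pr <- next_pow2(r0); pc <- next_pow2(c0)
  padded <- pad_matrix(img, pr, pc, mode = params$pad_mode)
  H <- tie_hom_filter(c(pr, pc), params)
  out <- Re(ifft2(fft2(padded) * H))
  out[seq_len(r0), seq_len(c0), drop = FALSE]
}

#' Apply the TIE forward model (fringe synthesis)
#'
#' The inverse of [phase_retrieve()]: divides the spectrum by the TIE-Hom
#' response, synthesising the propagation fringes that a detector at
#' distance `z` would record for a homogeneous object. Used by the
#' acquisition simulator and in round-trip tests.
#'
#' @inheritParams phase_retrieve
#' @param crop Return the original shape (default). With `crop = FALSE` the
#'   full padded power-of-two field is returned, on which
#'   [phase_retrieve()] inverts the forward model exactly (its own padding
#'   step is then the identity); the original image is the top-left crop.
#' @return Fringed intensity image; shape of `img`, or the padded shape
#'   when `crop = FALSE`.
#' @export
tie_forward <- function(img, params, crop = TRUE) {
  if (length(dim(img)) == 3L) {
    out <- array(0, dim(img))
    for (k in seq_len(dim(img)[3]))
      out[, , k] <- tie_forward(img[, , k], params, crop = crop)
    return(out)
  }
  r0 <- nrow(img); c0 <- ncol(img)
  pr <- next_pow2(r0); pc <- next_pow2(c0)
  padded <- pad_matrix(img, pr, pc, mode = params$pad_mode)
  H <- tie_hom_filter(c(pr, pc), params)
  out <- Re(ifft2(fft2(padded) / H))
  if (crop) out[seq_len(r0), seq_len(c0), drop = FALSE] else out
}

#' Beam-hardening correction
#'
#' Second-order polynomial linearisation of the attenuation response of a
#' polychromatic beam: in the attenuation domain the line integrals
#' `p = -log(I_cor)` are mapped to `p + c2 * p^2` (values clamped at 0
#' first); in the intensity domain the same map is applied to the intensity
#' values directly. `c2 = 0` is the identity; increase `c2` iteratively
#' until cupping in a uniform region of the reconstruction is minimised.
#'
#' @param x Image or stack, in the domain declared by `params`.
#' @param params A [bh_params()].
#' @return Corrected image/stack.
#' @export
beam_hardening_correct <- function(x, params) {
  stopifnot(inherits(params, "bh_params"))
  if (params$domain == "attenuation") x <- pmax(x, 0)
  x + params$c2 * x^2
}
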