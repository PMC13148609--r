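#' Reconstruction filter registry
#'
#' Frequency responses for filtered back-projection, defined on the FFT
#' frequency grid in cycles per sample (Nyquist `f_N = 0.5`), each the ramp
#' `|f|` shaped by an apodising window:
#'
#' * `ramlak`      — `|f|` (sharpest, no apodisation)
#' * `shepp_logan` — `|f| * sinc(f / (2 f_N))`
#' * `cosine`      — `|f| * cos(pi * f / (2 f_N))`
#' * `hamming`     — `|f| * (0.54 + 0.46 cos(pi * f / f_N))`
#' * `hann`        — `|f| * (0.5 + 0.5 cos(pi * f / f_N))`
#'
#' All responses are 0 at zero frequency and are zeroed above
#' `cutoff_frac * f_N`. The registry is extensible via [register_filter()].
#'
#' @name recon-filters
NULL

.filter_registry <- new.env(parent = emptyenv())

#' Register a reconstruction filter window
#'
#' @param name Filter name.
#' @param window Function of `q = |f| / f_N` in `[0, 1]` returning the
#'   apodising window multiplying the ramp `|f|`.
#' @return Invisibly, `name`.
#' @export
register_filter <- function(name, window) {
  stopifnot(is.character(name), is.function(window))
  assign(name, window, envir = .filter_registry)
  invisible(name)
}

register_filter("ramlak", function(q) rep(1, length(q)))
register_filter("shepp_logan", function(q) {
  out <- rep(1, length(q))
  nz <- q != 0
  out[nz] <- sin(pi * q[nz] / 2) / (pi * q[nz] / 2)
  out
})
register_filter("cosine", function(q) cos(pi * q / 2))
register_filter("hamming", function(q) 0.54 + 0.46 * cos(pi * q))
register_filter("hann", function(q) 0.5 + 0.5 * cos(pi * q))

#' List registered reconstruction filters
#' @return Character vector of filter names.
#' @export
list_filters <- function() sort(ls(.filter_registry))

#' Reconstruction filter specification
#'
#' @param name One of [list_filters()].
#' @param cutoff_frac Fraction of the Nyquist frequency above which the
#'   response is zeroed, in `(0, 1]`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(name = "ramlak", cutoff_frac = 1) {
  if (!name %in% list_filters())
    stop("unknown filter '", name, "'; registered: ",
         paste(list_filters(), collapse = ", "))
  stopifnot(cutoff_frac > 0, cutoff_frac <= 1)
  structure(list(name = name, cutoff_frac = cutoff_frac),
            class = "filter_spec")
}

#' Build a 1-D reconstruction filter response
#'
#' @param spec A [filter_spec()].
#' @param n Even padded FFT length.
#' @return Numeric vector of length `n`: the response at the FFT sample
#'   frequencies (cycles per sample), ramp times window, zero beyond the
#'   cutoff, exactly 0 at zero frequency.
#' @export
build_filter <- function(spec, n) {
  stopifnot(inherits(spec, "filter_spec"), n >= 2L, n %% 2L == 0L)
  f <- fft_freqs(n)
  fN <- 0.5
  q <- abs(f) / fN
  window <- get(spec$name, envir = .filter_registry)
  resp <- abs(f) * window(q)
  resp[abs(f) > spec$cutoff_frac * fN + 1e-12] <- 0
  resp
}
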