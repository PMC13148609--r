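# Shared numerics: padding, 2-D FFT helpers, phase correlation, shifts.

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2L^as.integer(ceiling(log2(n)))
}

# Pad a matrix to (rows, cols) with edge replication or reflection.
# The original image sits in the top-left corner; padding extends right/down
# (plus symmetric wrap handled by the FFT periodicity).
pad_matrix <- function(m, rows, cols, mode = c("edge", "reflect")) {
  mode <- match.arg(mode)
  r0 <- nrow(m); c0 <- ncol(m)
  stopifnot(rows >= r0, cols >= c0)
  if (rows == r0 && cols == c0) return(m)
  idx_pad <- function(n0, n, mode) {
    extra <- n - n0
    if (extra == 0L) return(seq_len(n0))
    if (mode == "edge") {
      c(seq_len(n0), rep.int(n0, extra))
    } else {
      # reflect without repeating the edge sample, tiling as needed
      refl <- c(seq_len(n0), rev(seq_len(n0))[-1][-(n0 - 1)])
      if (length(refl) < 2L) refl <- seq_len(n0)
      c(seq_len(n0), refl[((n0 + seq_len(extra) - 1L) %% length(refl)) + 1L])
    }
  }
  m[idx_pad(r0, rows, mode), idx_pad(c0, cols, mode), drop = FALSE]
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# FFT sample frequencies in cycles per sample (like numpy.fft.fftfreq).
fft_freqs <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

# Translation between two equally shaped matrices by Fourier correlation.
# Returns the sub-pixel shift (dy, dx) such that b is a copy of a translated
# by that amount, plus a confidence = peak / second peak.
#
# `whiten` is the spectral-normalisation exponent of generalised cross
# correlation: 1 = pure phase correlation (sharp peak, best for textured
# content such as montage overlaps), 0 = plain cross correlation (broad,
# noise-robust peak, better for smooth projection data).
phase_correlate <- function(a, b, subpixel = TRUE, whiten = 1) {
  stopifnot(all(dim(a) == dim(b)))
  nr <- nrow(a); nc <- ncol(a)
  a <- a - mean(a); b <- b - mean(b)
  # mild Hann taper reduces wrap-around leakage in windowed sub-regions;
  # axes too short to taper meaningfully are left untouched
  taper <- function(n) {
    if (n < 8) rep(1, n)
    else 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  }
  w <- outer(taper(nr), taper(nc))
  FA <- fft2(a * w); FB <- fft2(b * w)
  cp <- FA * Conj(FB)
  if (whiten > 0) {
    mag <- Mod(cp)
    cp <- cp / pmax(mag, .Machine$double.eps)^whiten
  }
  r <- Re(ifft2(cp))
  pk <- which.max(r)
  pi_ <- ((pk - 1L) %% nr) + 1L
  pj_ <- ((pk - 1L) %/% nr) + 1L
  peak_val <- r[pi_, pj_]
  # second peak outside an exclusion zone scaled to the peak width (broad
  # for unwhitened correlation)
  hw_i <- max(2L, nr %/% 16L); hw_j <- max(2L, nc %/% 16L)
  excl_i <- ((pi_ - 1L - hw_i):(pi_ - 1L + hw_i)) %% nr + 1L
  excl_j <- ((pj_ - 1L - hw_j):(pj_ - 1L + hw_j)) %% nc + 1L
  r2 <- r
  r2[excl_i, excl_j] <- -Inf
  second <- max(r2)
  confidence <- if (is.finite(second) && second > 0) peak_val / second else Inf

  wrap <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
  dy <- wrap(pi_, nr); dx <- wrap(pj_, nc)
  if (subpixel) {
    # refine around the integer peak by direct DFT evaluation on an
    # upsampled local grid (+/- 1 px at 1/upsample resolution)
    upsample <- 20L
    ys <- if (nr > 2) dy + seq(-1, 1, by = 1 / upsample) else dy
    xs <- if (nc > 2) dx + seq(-1, 1, by = 1 / upsample) else dx
    ky <- fft_freqs(nr) * nr
    kx <- fft_freqs(nc) * nc
    EY <- exp(2i * pi * outer(ys, ky) / nr)
    EX <- exp(2i * pi * outer(kx, xs) / nc)
    r_up <- Re(EY %*% cp %*% EX) / (nr * nc)
    up_pk <- which(r_up == max(r_up), arr.ind = TRUE)[1, ]
    dy <- ys[up_pk[1]]; dx <- xs[up_pk[2]]
  }
  # positive (dy, dx): b appears shifted by (-dy, -dx) relative to a, i.e.
  # a(y, x) matches b(y - dy, x - dx)
  list(dy = dy, dx = dx, confidence = as.numeric(confidence))
}

# Horizontal sub-pixel translation of a matrix by `shift_px` columns
# (positive moves content to the right), linear interpolation, edge padded.
shift_columns <- function(m, shift_px) {
  if (shift_px == 0) return(m)
  nc <- ncol(m)
  src <- seq_len(nc) - shift_px          # sample source column per output col
  j0 <- floor(src)
  fr <- src - j0
  j0c <- pmin(pmax(j0, 1L), nc)
  j1c <- pmin(pmax(j0 + 1L, 1L), nc)
  m[, j0c, drop = FALSE] * rep(1 - fr, each = nrow(m)) +
    m[, j1c, drop = FALSE] * rep(fr, each = nrow(m))
}

# Median of a 3x3 (or wider) neighbourhood, computed via shifted copies;
# edges use edge replication. Returns matrix of local medians.
local_median <- function(m, window = 3L) {
  stopifnot(window %% 2L == 1L, window >= 3L)
  h <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- function(s) pmin(pmax(seq_len(nr) + s, 1L), nr)
  cidx <- function(s) pmin(pmax(seq_len(nc) + s, 1L), nc)
  shifts <- expand.grid(dr = -h:h, dc = -h:h)
  stackv <- vapply(seq_len(nrow(shifts)), function(k) {
    as.numeric(m[ridx(shifts$dr[k]), cidx(shifts$dc[k])])
  }, numeric(nr * nc))
  med <- apply(stackv, 1L, stats::median)
  matrix(med, nr, nc)
}

# Odd-width running median along a vector with edge replication,
# wrapping stats::runmed.
run_median <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  if (length(x) <= width) return(rep(stats::median(x), length(x)))
  as.numeric(stats::runmed(x, width, endrule = "median"))
}
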