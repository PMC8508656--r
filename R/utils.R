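# Low-level numeric helpers shared by the simulator, deconvolution and
# measurement stages.  All distances are in nm unless a name says otherwise.

# FWHM of a Gaussian = 2 sqrt(2 ln 2) * sigma
FWHM_CONST <- 2 * sqrt(2 * log(2))

#' Convert between Gaussian sigma and FWHM
#'
#' The full width at half maximum of a Gaussian of width parameter
#' \eqn{\sigma} is \eqn{2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma}.
#'
#' @param fwhm,sigma Width in any length unit; the same unit is returned.
#' @return A numeric vector in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_CONST

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) FWHM_CONST * sigma

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' simulation functions are deterministic without polluting the session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

gaussian_kernel_1d <- function(sigma_px, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma_px))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

#' Gaussian blur of a matrix (reflect-padded, FFT-based)
#'
#' Convolves a matrix with an isotropic 2D Gaussian.  The input is
#' reflect-padded by the kernel support before the circular FFT
#' convolution and cropped afterwards, so image content never wraps
#' around and total intensity is conserved away from the borders.
#'
#' @param mat Numeric matrix.
#' @param sigma_px Gaussian sigma in pixels of `mat`.  Values below 0.05
#'   return the input unchanged (sub-sample blur is a no-op on the grid).
#' @return Matrix of the same dimension.
#' @export
gauss_blur <- function(mat, sigma_px) {
  stopifnot(is.matrix(mat), is.numeric(mat), sigma_px >= 0)
  if (sigma_px < 0.05) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- max(2L, ceiling(4 * sigma_px))
  # reflect padding
  ri <- c(rev(seq_len(min(pad, nr))), seq_len(nr), nr + 1 - seq_len(min(pad, nr)))
  ci <- c(rev(seq_len(min(pad, nc))), seq_len(nc), nc + 1 - seq_len(min(pad, nc)))
  padr <- length(ri) - nr - min(pad, nr)  # actual leading pad sizes
  p1 <- min(pad, nr); p2 <- min(pad, nc)
  ext <- mat[ri, ci, drop = FALSE]
  P1 <- stats::nextn(nrow(ext), c(2, 3, 5))
  P2 <- stats::nextn(ncol(ext), c(2, 3, 5))
  big <- matrix(0, P1, P2)
  big[seq_len(nrow(ext)), seq_len(ncol(ext))] <- ext
  k <- gaussian_kernel_1d(sigma_px, radius = pad)
  kr <- numeric(P1); kc <- numeric(P2)
  idx1 <- ((-pad):pad) %% P1 + 1L
  idx2 <- ((-pad):pad) %% P2 + 1L
  kr[idx1] <- kr[idx1] + k
  kc[idx2] <- kc[idx2] + k
  K <- outer(kr, kc)
  out <- Re(stats::fft(stats::fft(big) * stats::fft(K), inverse = TRUE)) / (P1 * P2)
  out[p1 + seq_len(nr), p2 + seq_len(nc), drop = FALSE]
}

# Block-mean binning of a matrix by integer factor f (dims must divide).
bin_matrix <- function(mat, f) {
  f <- as.integer(f)
  stopifnot(f >= 1, nrow(mat) %% f == 0, ncol(mat) %% f == 0)
  if (f == 1L) return(mat)
  nr <- nrow(mat) %/% f
  nc <- ncol(mat) %/% f
  m2 <- rowsum(mat, rep(seq_len(nr), each = f))
  m3 <- t(rowsum(t(m2), rep(seq_len(nc), each = f)))
  m3 / (f * f)
}

#' Bilinear interpolation of matrix values
#'
#' Samples a matrix at sub-pixel positions.  Pixel centres sit at integer
#' coordinates: element `mat[i, j]` is at `(row = i, col = j)`.
#' Coordinates are clamped to the valid range.
#'
#' @param mat Numeric matrix.
#' @param row,col Numeric vectors of sampling positions (same length).
#' @return Numeric vector of interpolated values.
#' @export
bilinear_sample <- function(mat, row, col) {
  stopifnot(length(row) == length(col))
  nr <- nrow(mat); nc <- ncol(mat)
  r <- pmin(pmax(row, 1), nr)
  cc <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  mat[i00] * (1 - fr) * (1 - fc) + mat[i10] * fr * (1 - fc) +
    mat[i01] * (1 - fr) * fc + mat[i11] * fr * fc
}

# in-bounds check for bilinear sampling without clamping artefacts
in_bounds <- function(mat, row, col) {
  row >= 1 & row <= nrow(mat) & col >= 1 & col <= ncol(mat)
}

# Catmull-Rom weights for fractional offset t in [0,1]
cr_weights <- function(t) {
  list(`-1` = -0.5 * t^3 + t^2 - 0.5 * t,
       `0`  =  1.5 * t^3 - 2.5 * t^2 + 1,
       `1`  = -1.5 * t^3 + 2 * t^2 + 0.5 * t,
       `2`  =  0.5 * t^3 - 0.5 * t^2)
}

#' Cubic (Catmull-Rom) interpolation of matrix values
#'
#' Interpolating bicubic sampling at sub-pixel positions.  Unlike bilinear
#' interpolation, the Catmull-Rom kernel adds essentially no blur of its
#' own, which matters when measuring widths close to the pixel size.
#' Same coordinate convention as [bilinear_sample()].
#'
#' @inheritParams bilinear_sample
#' @return Numeric vector of interpolated values.
#' @export
cubic_sample <- function(mat, row, col) {
  stopifnot(length(row) == length(col))
  nr <- nrow(mat); nc <- ncol(mat)
  r <- pmin(pmax(row, 1), nr)
  cc <- pmin(pmax(col, 1), nc)
  r0 <- pmin(pmax(floor(r), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(cc), 1L), nc - 1L)
  wr <- cr_weights(r - r0)
  wc <- cr_weights(cc - c0)
  out <- numeric(length(r))
  for (dr in -1:2) {
    ri <- pmin(pmax(r0 + dr, 1L), nr)
    wri <- wr[[as.character(dr)]]
    for (dc in -1:2) {
      ci <- pmin(pmax(c0 + dc, 1L), nc)
      out <- out + wri * wc[[as.character(dc)]] * mat[cbind(ri, ci)]
    }
  }
  out
}
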