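# Independent numerical oracles.  These deliberately avoid the package's
# rendering/fitting code paths: dense grids, direct convolution via
# Gaussian CDFs, and direct half-maximum width measurement.

# FWHM (by direct half-max crossing) of a top-hat of width w convolved
# with a Gaussian PSF of the given FWHM, optionally followed by detector
# box integration of width `box`.
oracle_tophat_fwhm <- function(w_nm, psf_fwhm_nm, box_nm = NULL, dx = 0.05) {
  s <- psf_fwhm_nm / (2 * sqrt(2 * log(2)))
  x <- seq(-6 * s - w_nm, 6 * s + w_nm, by = dx)
  y <- pnorm((x + w_nm / 2) / s) - pnorm((x - w_nm / 2) / s)
  if (!is.null(box_nm)) {
    k <- round(box_nm / dx)
    y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    y[is.na(y)] <- 0
  }
  half <- max(y) / 2
  ab <- which(y >= half)
  i1 <- ab[1]; i2 <- ab[length(ab)]
  xl <- stats::approx(y[(i1 - 1):i1], x[(i1 - 1):i1], xout = half)$y
  xr <- stats::approx(y[i2:(i2 + 1)], x[i2:(i2 + 1)], xout = half)$y
  xr - xl
}

# Brute-force Costes threshold: naive descending scan over the unique
# intensities of ch1, re-evaluating the below-set Pearson at each step.
oracle_costes_t1 <- function(ch1, ch2, a, b) {
  cand <- sort(unique(as.vector(ch1)), decreasing = TRUE)
  for (T1 in cand) {
    bel <- ch1 < T1 & ch2 < a * T1 + b
    if (sum(bel) < 2) return(T1)
    s1 <- stats::sd(ch1[bel]); s2 <- stats::sd(ch2[bel])
    if (s1 == 0 || s2 == 0) return(T1)
    if (stats::cor(ch1[bel], ch2[bel]) <= 0) return(T1)
  }
  cand[length(cand)]
}

# Closed-form Welch statistic, Satterthwaite dof and two-sided p,
# evaluated directly from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

# 1D Gaussian-cross-section band rendered through the package's blur on a
# row-uniform matrix; returns a line_profile at the supersample pitch.
gaussian_band_profile <- function(sigma_t_nm, psf_fwhm_nm, ss_nm = 5) {
  s_t <- sigma_t_nm / ss_nm
  s_p <- (psf_fwhm_nm / (2 * sqrt(2 * log(2)))) / ss_nm
  half <- ceiling(6 * (s_t + s_p))
  n <- 2 * half + 1
  x <- ((1:n) - half - 1) * ss_nm
  band <- exp(-(x / ss_nm)^2 / (2 * s_t^2))
  m <- matrix(rep(band, 9), nrow = 9, byrow = TRUE)
  bl <- gauss_blur(m, s_p)
  list(distance_nm = x, intensity = bl[5, ])
}
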