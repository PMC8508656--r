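# Forward imaging model: Gaussian PSF blur at the supersampled grid,
# detector-pixel integration, photon scaling, Poisson shot noise and
# Gaussian read noise.

#' Render a ground-truth scene through an optical configuration
#'
#' Each channel map is convolved with an isotropic Gaussian PSF of the
#' configured lateral FWHM, box-integrated to detector pixels, and scaled
#' jointly so the brightest noiseless lamina pixel (across both channels,
#' in-focus slice) has expectation `photons_peak`.  For each z-slice the
#' expectation is weighted by an axial Gaussian centred on the focal
#' (middle) slice, then Poisson shot noise is applied, Gaussian read noise
#' added, and the result rounded to integer counts and clipped at zero
#' (photon-counting detector).
#'
#' @param gt A [build_lamina_scene()] result.
#' @param optics An [optics_config()].
#' @param noiseless If `TRUE`, return the noiseless expectation (float)
#'   instead of noisy counts.
#' @param seed Seed for the noise stream; defaults to `optics$seed`.
#' @return An [image_stack()] with channels `"laminA"`, `"laminB1"`.
#' @export
render_image <- function(gt, optics, noiseless = FALSE, seed = optics$seed) {
  stopifnot(inherits(gt, "ground_truth"), inherits(optics, "optics_config"))
  if (all(gt$channel_maps[[1]] == 0) && all(gt$channel_maps[[2]] == 0)) {
    stop("empty ground truth: both channel maps are all zero")
  }
  ss <- gt$supersample_nm
  f <- optics$pixel_size_nm / ss
  if (abs(f - round(f)) > 1e-9) {
    stop("supersample pitch (", ss, " nm) must divide pixel_size_nm (",
         optics$pixel_size_nm, " nm)")
  }
  f <- as.integer(round(f))
  sigma_ss <- fwhm_to_sigma(optics$psf_fwhm_lateral_nm) / ss
  maps <- gt$channel_maps
  nr <- (nrow(maps[[1]]) %/% f) * f
  nc <- (ncol(maps[[1]]) %/% f) * f
  binned <- lapply(maps, function(m) {
    b <- bin_matrix(gauss_blur(m, sigma_ss)[seq_len(nr), seq_len(nc), drop = FALSE], f)
    pmax(b, 0)  # clip FFT round-off
  })
  peak <- max(vapply(binned, max, numeric(1)))
  if (peak <= 0) stop("empty ground truth after rendering")
  scale <- optics$photons_peak / peak
  nz <- optics$z_slices
  mid <- (nz + 1) / 2
  sig_ax <- fwhm_to_sigma(optics$psf_fwhm_axial_nm)
  zw <- exp(-((seq_len(nz) - mid) * optics$z_step_nm)^2 / (2 * sig_ax^2))
  npy <- nr %/% f; npx <- nc %/% f
  pix <- array(0, dim = c(2L, nz, npy, npx))
  for (ch in 1:2) {
    for (z in seq_len(nz)) {
      pix[ch, z, , ] <- binned[[ch]] * scale * zw[z]
    }
  }
  if (!noiseless) {
    pix <- with_seed(seed, {
      counts <- stats::rpois(length(pix), lambda = as.vector(pix))
      counts <- counts + stats::rnorm(length(pix), sd = optics$read_noise_sd)
      array(pmax(round(counts), 0), dim = dim(pix))
    })
  }
  axes <- NULL
  if (!is.null(gt$axes_nm)) {
    grp <- function(v) {
      vv <- v[seq_len(length(v) %/% f * f)]
      as.vector(rowsum(vv, rep(seq_len(length(vv) %/% f), each = f))) / f
    }
    axes <- list(x = grp(gt$axes_nm$x[seq_len(nc)]),
                 y = grp(gt$axes_nm$y[seq_len(nr)]))
  }
  image_stack(pix,
              channel_names = c("laminA", "laminB1"),
              pixel_size_nm = optics$pixel_size_nm,
              z_step_nm = optics$z_step_nm,
              provenance = sprintf(
                "simulated %s view, %s optics (PSF %g nm), thickness %g nm, rho %g, offset %g nm, seed %d, %s",
                gt$view, optics$modality, optics$psf_fwhm_lateral_nm,
                gt$true_thickness_nm, gt$shared_fraction, gt$radial_offset_nm,
                as.integer(seed), if (noiseless) "noiseless" else "noisy"),
              axes_nm = axes)
}

#' Ground-truth Pearson correlation of the rendered expectations
#'
#' The correlation the optics would report with unlimited photons:
#' Pearson's r of the two noiseless, PSF-blurred, pixel-binned channel
#' expectations (in-focus slice) over pixels where either channel exceeds
#' 1\% of its maximum.  Serves as the known answer when validating
#' colocalization recovery.
#'
#' @inheritParams render_image
#' @return Correlation in `[-1, 1]`.
#' @export
true_pearson <- function(gt, optics) {
  st <- render_image(gt, optics, noiseless = TRUE)
  mid <- (dim(st$pixels)[2] + 1) %/% 2
  a <- st$pixels[1, mid, , ]
  b <- st$pixels[2, mid, , ]
  mask <- a > 0.01 * max(a) | b > 0.01 * max(b)
  av <- a[mask]; bv <- b[mask]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop("constant channel: correlation undefined")
  }
  stats::cor(av, bv)
}
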