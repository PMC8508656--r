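test_that("SNR follows the histogram-extremes formula", {
  expect_equal(estimate_snr(matrix(c(900, 1, 5, 10), 2)), 90)
  expect_equal(estimate_snr(matrix(3, 2, 2)), 3)
  # zeros are ignored: smallest strictly positive value is the divisor
  expect_equal(estimate_snr(matrix(c(0, 4, 100, 50), 2)), 15)
  expect_error(estimate_snr(matrix(0, 3, 3)), "all-zero")
})

test_that("a delta PSF leaves the image unchanged at any iteration count", {
  img <- matrix(runif(400, 1, 10), 20)
  cfg <- deconv_config(psf_fwhm_nm = 0.01, pixel_size_nm = 10,
                       max_iterations = 7, snr = 100)
  expect_equal(richardson_lucy(img, cfg), img, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a flat image is a fixed point of the iteration", {
  flat <- matrix(5, 40, 40)
  out <- richardson_lucy(flat, deconv_config(80, 10, max_iterations = 10,
                                             snr = 1e6))
  expect_equal(max(abs(out - 5)), 0, tolerance = 1e-12)
})

test_that("restoration sharpens a blurred point source monotonically", {
  n <- 65
  m <- matrix(0, n, n); m[33, 33] <- 100
  blurred <- gauss_blur(m, 3)             # sigma 3 px = 30 nm at 10 nm px
  input_fwhm <- sigma_to_fwhm(3) * 10
  fw <- vapply(c(1, 2, 5, 10, 20, 30, 40), function(k) {
    out <- richardson_lucy(blurred, deconv_config(input_fwhm, 10,
                                                  max_iterations = k,
                                                  snr = 1e6))
    expect_true(all(out >= 0))
    expect_equal(sum(out), sum(blurred), tolerance = 0.01)
    fit_gaussian_profile(list(distance_nm = ((1:n) - 33) * 10,
                              intensity = out[33, ]))$fwhm
  }, numeric(1))
  expect_true(all(fw < input_fwhm))
  expect_true(all(diff(fw) <= 1e-6))
})

test_that("the SNR-derived stopping rule halts noisy restorations early", {
  img <- matrix(rpois(900, 20), 30)
  cfg <- deconv_config(60, 30, max_iterations = 40, snr = 5)  # tol 1/25
  out <- richardson_lucy(img, cfg)
  expect_lt(attr(out, "iterations"), 40L)
  cfg2 <- deconv_config(60, 30, max_iterations = 40, snr = 1e6)
  out2 <- richardson_lucy(img, cfg2)
  expect_equal(attr(out2, "iterations"), 40L)
})

test_that("invalid inputs are rejected", {
  expect_error(deconv_config(-5, 10), "psf_fwhm_nm")
  expect_error(richardson_lucy(matrix(c(-5, 1, 2, 3), 2),
                               deconv_config(60, 30, snr = 10)),
               "nonnegative")
})

test_that("deconvolving a stack preserves its geometry and sharpens the rim", {
  gt <- build_lamina_scene(tiny_mid_config(modulation_amplitude = 0), seed = 3)
  st <- render_image(gt, sted_optics(seed = 8))
  dec <- deconvolve_stack(st, psf_fwhm_nm = 60, max_iterations = 10)
  expect_identical(dim(dec$pixels), dim(st$pixels))
  pre <- measure_thickness(st, channel = 1, expected_fwhm_nm = 60)
  post <- measure_thickness(dec, channel = 1, expected_fwhm_nm = 60)
  expect_lte(post$mean_nm, pre$mean_nm)
})
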