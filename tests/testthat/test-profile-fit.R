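test_that("a clean Gaussian recovers sigma and the exact FWHM constant", {
  for (sigma in c(40, 100, 150)) {
    x <- seq(-5 * sigma, 5 * sigma, length.out = 121)
    fit <- fit_gaussian_profile(list(distance_nm = x,
                                     intensity = 3 * exp(-x^2 / (2 * sigma^2))))
    expect_true(fit$converged)
    expect_equal(fit$sigma, sigma, tolerance = 1e-6)
    # the FWHM formula is an identity of the returned object
    expect_identical(fit$fwhm, 2 * sqrt(2 * log(2)) * fit$sigma)
  }
})

test_that("fitted width of a PSF-blurred thin shell matches the direct-width oracle", {
  prof <- gaussian_band_profile(0.01, 60)          # essentially the bare PSF
  prof$intensity <- pnorm((prof$distance_nm + 7) / fwhm_to_sigma(60)) -
                    pnorm((prof$distance_nm - 7) / fwhm_to_sigma(60))
  fit <- fit_gaussian_profile(prof)
  expect_true(fit$converged)
  oracle <- oracle_tophat_fwhm(14, 60)
  expect_equal(fit$fwhm, oracle, tolerance = 0.02)
})

test_that("degenerate profiles fail softly, bad inputs fail loudly", {
  x <- seq(-200, 200, by = 10)
  flat <- fit_gaussian_profile(list(distance_nm = x,
                                    intensity = rep(2, length(x))))
  expect_false(flat$converged)
  expect_match(flat$diagnostics, "constant")
  expect_error(fit_gaussian_profile(list(distance_nm = 1:10,
                                         intensity = rnorm(10))),
               "15 samples")
  oob <- structure(list(distance_nm = x, intensity = rep(NA_real_, length(x)),
                        out_of_bounds = TRUE), class = "line_profile")
  expect_false(fit_gaussian_profile(oob)$converged)
})

test_that("the two-level step baseline is recovered on both sides", {
  x <- seq(-400, 400, by = 8)
  sigma <- 90
  y <- 5 * exp(-x^2 / (2 * sigma^2)) +
    0.8 + (0.1 - 0.8) * pnorm(x / sigma)
  fit <- fit_gaussian_profile(list(distance_nm = x, intensity = y))
  expect_true(fit$converged)
  expect_equal(fit$baseline_in, 0.8, tolerance = 0.02)
  expect_equal(fit$baseline_out, 0.1, tolerance = 0.02)
  expect_equal(fit$sigma, sigma, tolerance = 1)
  single <- fit_gaussian_profile(list(distance_nm = x, intensity = y),
                                 single_baseline = TRUE)
  expect_true(single$baseline_in == single$baseline_out)
})

test_that("noisy fits below the R^2 threshold are marked unconverged", {
  set.seed(99)
  x <- seq(-300, 300, by = 10)
  y <- 0.2 * exp(-x^2 / (2 * 80^2)) + rnorm(length(x), 0, 1)
  fit <- fit_gaussian_profile(list(distance_nm = x, intensity = y))
  expect_false(fit$converged)
})

test_that("fit methods are mutually consistent", {
  x <- seq(-300, 300, by = 10)
  set.seed(1)
  y <- 4 * exp(-(x - 20)^2 / (2 * 70^2)) + 0.5 + rnorm(length(x), 0, 0.02)
  fit <- fit_gaussian_profile(list(distance_nm = x, intensity = y))
  expect_true(fit$converged)
  expect_named(coef(fit), c("amplitude", "center", "sigma", "baseline_in",
                            "baseline_out", "fwhm"))
  expect_equal(predict(fit), fit$fitted, tolerance = 1e-12)
  expect_equal(residuals(fit), y - fit$fitted, tolerance = 1e-12)
  expect_lt(sd(residuals(fit)), 0.03)
  expect_output(print(fit), "FWHM")
  expect_output(print(summary(fit)), "converged")
})
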