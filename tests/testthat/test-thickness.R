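test_that("identical positions give zero spread", {
  x <- seq(-300, 300, by = 10)
  prof <- list(distance_nm = x, intensity = exp(-x^2 / (2 * 80^2)))
  fwhm <- vapply(1:5, function(i) fit_gaussian_profile(prof)$fwhm, numeric(1))
  expect_equal(sd(fwhm), 0)
})

test_that("confocal reads a thicker layer than STED on the same scene", {
  gt <- build_lamina_scene(tiny_mid_config(), seed = 4)
  res <- lapply(c("sted", "confocal"), function(mod) {
    opt <- optics_config(mod, seed = 21)
    st <- render_image(gt, opt, noiseless = TRUE)
    measure_thickness(st, channel = 1,
                      expected_fwhm_nm = opt$psf_fwhm_lateral_nm,
                      modality = mod)
  })
  expect_gt(res[[2]]$mean_nm, res[[1]]$mean_nm)
  expect_identical(res[[1]]$n_attempted, 5L)
})

test_that("mean FWHM is stable across noisy replicates", {
  gt <- build_lamina_scene(tiny_mid_config(), seed = 6)
  means <- vapply(1:20, function(s) {
    st <- render_image(gt, sted_optics(seed = 1000 + s))
    measure_thickness(st, channel = 1, expected_fwhm_nm = 60)$mean_nm
  }, numeric(1))
  expect_lt(sd(means), 0.1 * mean(means))
})

test_that("unmeasurable cells raise an error instead of returning numbers", {
  gt <- build_lamina_scene(tiny_mid_config(), seed = 2)
  st <- render_image(gt, sted_optics(seed = 3))
  expect_error(
    measure_thickness(st, channel = 1, half_length_nm = 1e5),
    "no measurable positions")
})

test_that("per-position records carry the documented columns", {
  gt <- build_lamina_scene(tiny_mid_config(), seed = 2)
  st <- render_image(gt, sted_optics(seed = 3))
  res <- measure_thickness(st, channel = "laminA", expected_fwhm_nm = 60,
                           cell_id = "c7", modality = "sted")
  rec <- thickness_records(res)
  expect_identical(names(rec),
                   c("cell_id", "channel", "modality", "position", "fwhm_nm",
                     "r2", "used"))
  expect_identical(nrow(rec), 5L)
  expect_identical(unique(rec$cell_id), "c7")
  expect_equal(mean(rec$fwhm_nm[rec$used]), res$mean_nm)
  expect_output(print(res), "FWHM")
})

test_that("the pixelation correction removes the detector-box variance", {
  gt <- build_lamina_scene(tiny_mid_config(), seed = 5)
  st <- render_image(gt, sted_optics(seed = 9), noiseless = TRUE)
  raw <- measure_thickness(st, channel = 1, expected_fwhm_nm = 60,
                           pixel_correction = FALSE)
  cor <- measure_thickness(st, channel = 1, expected_fwhm_nm = 60)
  s2_raw <- fwhm_to_sigma(raw$mean_nm)^2
  s2_cor <- fwhm_to_sigma(cor$mean_nm)^2
  expect_equal(s2_raw - s2_cor, st$pixel_size_nm^2 / 12, tolerance = 1)
})
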