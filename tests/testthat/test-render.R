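test_that("identity optics reproduce the bin-averaged ground truth", {
  gt <- build_lamina_scene(tiny_top_config(nucleoplasm_level = 0), seed = 2)
  expect_warning(opt <- sted_optics(psf_fwhm_lateral_nm = 0.5, z_slices = 1),
                 "undersamples")
  st <- render_image(gt, opt, noiseless = TRUE)
  f <- opt$pixel_size_nm / gt$supersample_nm
  m <- gt$channel_maps[[1]]
  nr <- (nrow(m) %/% f) * f; nc <- (ncol(m) %/% f) * f
  ref <- bin_matrix(m[seq_len(nr), seq_len(nc)], f)
  got <- st$pixels[1, 1, , ]
  expect_equal(got / max(got), ref / max(ref), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PSF convolution conserves total intensity", {
  gt <- build_lamina_scene(tiny_top_config(), seed = 4)
  m <- gt$channel_maps[[1]]
  for (fwhm in c(60, 241)) {
    sig <- fwhm_to_sigma(fwhm) / gt$supersample_nm
    expect_equal(sum(gauss_blur(m, sig)), sum(m), tolerance = 0.005)
  }
})

test_that("rendering is bit-stable for a fixed seed and configuration", {
  gt <- build_lamina_scene(tiny_top_config(), seed = 7)
  opt <- sted_optics(seed = 42)
  s1 <- render_image(gt, opt)
  s2 <- render_image(gt, opt)
  expect_identical(s1$pixels, s2$pixels)
  s3 <- render_image(gt, optics_config("sted", seed = 43))
  expect_false(identical(s1$pixels, s3$pixels))
})

test_that("rendered counts are integers and z-slices are axially weighted", {
  gt <- build_lamina_scene(tiny_top_config(), seed = 1)
  st <- render_image(gt, sted_optics(seed = 2))
  expect_true(all(st$pixels == round(st$pixels)))
  expect_true(all(st$pixels >= 0))
  expect_equal(dim(st$pixels)[2], 3L)
  noiseless <- render_image(gt, sted_optics(seed = 2), noiseless = TRUE)
  expect_gt(sum(noiseless$pixels[1, 2, , ]), sum(noiseless$pixels[1, 1, , ]))
  expect_equal(sum(noiseless$pixels[1, 1, , ]), sum(noiseless$pixels[1, 3, , ]))
})

test_that("true channel correlation is 1 for identical channels and increases with sharing", {
  cfg1 <- tiny_top_config(shared_fraction = 1, radial_offset_nm = 0)
  expect_equal(true_pearson(build_lamina_scene(cfg1, seed = 1), sted_optics()),
               1.0, tolerance = 1e-12)
  for (s in 1:3) {
    r <- vapply(c(0, 0.5, 1), function(rho) {
      true_pearson(build_lamina_scene(tiny_top_config(shared_fraction = rho),
                                      seed = s), sted_optics())
    }, numeric(1))
    expect_true(r[1] < r[2] && r[2] < r[3])
  }
})

test_that("empty ground truth is rejected", {
  gt <- build_lamina_scene(tiny_top_config(), seed = 1)
  gt$channel_maps <- lapply(gt$channel_maps, function(m) m * 0)
  expect_error(render_image(gt, sted_optics()), "empty")
})
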