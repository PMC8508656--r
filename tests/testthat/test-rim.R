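test_that("traced rim lies within one pixel of the true shell centre line", {
  gt <- build_lamina_scene(tiny_mid_config(), seed = 2)
  st <- render_image(gt, sted_optics(seed = 5), noiseless = TRUE)
  rim <- segment_rim(get_plane(st, 1))
  truth <- gt_nm_to_px(st, gt$rim_polygon)
  d <- vapply(seq_len(nrow(rim$points)), function(i) {
    min(sqrt((truth[, 1] - rim$points[i, 1])^2 +
             (truth[, 2] - rim$points[i, 2])^2))
  }, numeric(1))
  expect_lt(mean(d), 1)
})

test_that("a blank image raises 'no nucleus found'", {
  expect_error(segment_rim(matrix(0, 50, 50)), "no nucleus")
  expect_error(segment_rim(matrix(rnorm(900, 10, 0.1), 30)), "no nucleus")
})

test_that("normals on a circular shell point radially", {
  n <- 220
  xs <- (1:n) - 110.5
  D <- sqrt(outer(xs^2, xs^2, "+"))
  img <- exp(-(D - 70)^2 / 18)
  rim <- segment_rim(img)
  v <- rim$points - matrix(c(110.5, 110.5), nrow(rim$points), 2, byrow = TRUE)
  radial <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(pmax(rowSums(radial * rim$normals), -1), 1)) * 180 / pi
  expect_lt(max(ang), 3)
  expect_equal(mean(sqrt(rowSums(v^2))), 70, tolerance = 0.01)
})

test_that("profile anchors sit at equal arc-length fractions", {
  n <- 220
  xs <- (1:n) - 110.5
  D <- sqrt(outer(xs^2, xs^2, "+"))
  img <- exp(-(D - 70)^2 / 18)
  rim <- segment_rim(img)
  profs <- sample_profiles(img, rim, pixel_size_nm = 30, n_positions = 5,
                           half_length_nm = 300)
  # on a circle, equal arc fractions are equal angular fractions
  ang <- vapply(profs, function(p) {
    atan2(p$anchor[1] - 110.5, p$anchor[2] - 110.5)
  }, numeric(1))
  gaps <- diff(sort(ang)) * 180 / pi
  expect_equal(gaps, rep(72, 4), tolerance = 3)
})

test_that("profiles of a constant image are constant", {
  n <- 220
  xs <- (1:n) - 110.5
  D <- sqrt(outer(xs^2, xs^2, "+"))
  ring <- exp(-(D - 70)^2 / 18)
  rim <- segment_rim(ring)
  flat <- matrix(7, n, n)
  profs <- sample_profiles(flat, rim, pixel_size_nm = 30, n_positions = 5,
                           half_length_nm = 300)
  for (p in profs) expect_true(all(abs(p$intensity - 7) < 1e-9))
})

test_that("profile peaks sit within half a PSF width of the rim crossing", {
  # uniform shell brightness: the local rim peak is the profile maximum
  gt <- build_lamina_scene(tiny_mid_config(modulation_amplitude = 0), seed = 3)
  st <- render_image(gt, sted_optics(seed = 6), noiseless = TRUE)
  plane <- get_plane(st, 1)
  rim <- segment_rim(plane)
  profs <- sample_profiles(plane, rim, st$pixel_size_nm, n_positions = 5,
                           half_length_nm = 210, spacing_nm = 10)
  for (p in profs) {
    peak_at <- p$distance_nm[which.max(p$intensity)]
    expect_lt(abs(peak_at), 30)  # PSF FWHM / 2
  }
})

test_that("a manual ROI polygon yields a usable rim", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  pts <- cbind(110.5 + 70 * cos(th), 110.5 + 70 * sin(th))
  rim <- rim_from_points(pts)
  expect_s3_class(rim, "nuclear_rim")
  v <- rim$points - matrix(c(110.5, 110.5), nrow(rim$points), 2, byrow = TRUE)
  expect_equal(mean(sqrt(rowSums(v^2))), 70, tolerance = 0.5)
  radial <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(pmax(rowSums(radial * rim$normals), -1), 1)) * 180 / pi
  expect_lt(max(ang), 3)
})

test_that("profiles leaving the image are flagged, not truncated", {
  n <- 220
  xs <- (1:n) - 110.5
  D <- sqrt(outer(xs^2, xs^2, "+"))
  img <- exp(-(D - 70)^2 / 18)
  rim <- segment_rim(img)
  profs <- sample_profiles(img, rim, pixel_size_nm = 30, n_positions = 5,
                           half_length_nm = 3000)
  expect_true(all(vapply(profs, function(p) p$out_of_bounds, logical(1))))
  expect_true(all(is.na(profs[[1]]$intensity)))
})
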