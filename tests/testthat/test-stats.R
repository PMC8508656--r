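test_that("Welch test matches the closed-form formulas", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  got <- welch_t_test(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(got$t_stat, ref$t, tolerance = 1e-12)
  expect_equal(got$dof, ref$dof, tolerance = 1e-12)
  expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  set.seed(3)
  x <- rnorm(8, 10, 2); y <- rnorm(12, 11, 4)
  got2 <- welch_t_test(x, y)
  ref2 <- oracle_welch(x, y)
  expect_equal(got2$t_stat, ref2$t, tolerance = 1e-12)
  expect_equal(got2$dof, ref2$dof, tolerance = 1e-12)
  expect_equal(got2$p_value, ref2$p, tolerance = 1e-12)
})

test_that("Welch test edge cases and symmetry", {
  a <- c(1, 2, 3)
  expect_equal(welch_t_test(a, a)$t_stat, 0)
  expect_equal(welch_t_test(a, a)$p_value, 1)
  expect_error(welch_t_test(1, a), "at least 2")
  set.seed(7)
  x <- rnorm(9); y <- rnorm(7, 1)
  f <- welch_t_test(x, y); r <- welch_t_test(y, x)
  expect_equal(f$t_stat, -r$t_stat)
  expect_equal(f$p_value, r$p_value)
  expect_equal(f$dof, r$dof)
})

test_that("significance stars follow the inclusive-threshold legend", {
  expect_identical(p_stars(c(0.004, 0.05, 0.2)), c("**", "*", "ns"))
  expect_identical(p_stars(c(1e-4, 1e-3, 0.01, 0.050001, 1)),
                   c("****", "***", "**", "ns", "ns"))
  expect_error(p_stars(1.5))
})

test_that("the comparison table aggregates per cell and tests pairwise", {
  set.seed(12)
  rec <- data.frame(
    group = rep(c("confocal", "sted"), each = 15),
    cell_id = rep(paste0("c", 1:6), each = 5),
    fwhm_nm = c(rnorm(15, 290, 20), rnorm(15, 130, 15)),
    used = TRUE)
  tab <- build_table(rec, value = "fwhm_nm", group = "group")
  expect_identical(nrow(tab$groups), 2L)
  expect_identical(tab$groups$n, c(3L, 3L))  # cells, not positions
  expect_identical(nrow(tab$tests), 1L)
  expect_lt(tab$tests$p_value, 0.05)
  expect_identical(tab$tests$stars, p_stars(tab$tests$p_value))
  # smallest measured value is taken over positions, not cell means
  expect_equal(tab$groups$smallest[tab$groups$group == "sted"],
               min(rec$fwhm_nm[rec$group == "sted"]))
  expect_output(print(tab), "Welch")
  # per-position mode uses every row as a unit
  tab2 <- build_table(rec, value = "fwhm_nm", group = "group",
                      aggregate_by = NULL)
  expect_identical(tab2$groups$n, c(15L, 15L))
  # single group: summaries only
  tab3 <- build_table(rec[rec$group == "sted", ], value = "fwhm_nm",
                      group = "group")
  expect_null(tab3$tests)
  paths <- write_comparison_table(tab, file.path(tempdir(), "tab"))
  expect_true(all(file.exists(paths)))
})

test_that("published Pearson values ship with the documented layout", {
  ref <- lamin_pearson_reference()
  expect_identical(dim(ref), c(6L, 2L))
  expect_identical(names(ref), c("cslm", "sted"))
  expect_true(all(ref$cslm > ref$sted))
})
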