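# Group comparisons: Welch's unequal-variance t-test and the usual
# significance-star convention, plus the table builder that aggregates
# per-cell measurements the way comparison tables are reported.

#' Welch's two-sided t-test
#'
#' Student's t-test for unequal variances (Welch statistic with
#' Satterthwaite degrees of freedom), two-sided.  Thin wrapper around
#' [stats::t.test()] returning just the three reported quantities.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values;
#'   at least one group must have nonzero variance.
#' @return List with `t_stat`, `dof`, `p_value`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t_stat = 0, dof = length(sample_a) + length(sample_b) - 2,
                  p_value = 1))
    }
    stop("both groups have zero variance")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE,
                      alternative = "two.sided")
  list(t_stat = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Significance stars for a p-value
#'
#' `* p <= 0.05, ** p <= 0.01, *** p <= 0.001, **** p <= 0.0001`;
#' boundaries are inclusive, anything above 0.05 is `"ns"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  vapply(p, function(pp) {
    if (pp <= 1e-4) "****"
    else if (pp <= 1e-3) "***"
    else if (pp <= 0.01) "**"
    else if (pp <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Build a group-comparison table
#'
#' Aggregates measurement rows into per-group mean +/- SD with n, runs all
#' pairwise Welch t-tests, and reports the smallest measured value per
#' group (for FWHM data this is the dataset's effective-resolution
#' statistic).  By default values are first averaged per cell, so cells --
#' not positions -- are the unit of replication; set
#' `aggregate_by = NULL` to test per-position values instead.  No
#' multiple-testing correction is applied (raw p-values are reported).
#'
#' @param records Data.frame of measurement rows.
#' @param value Name of the value column (default `"fwhm_nm"`).
#' @param group Name of the grouping column.
#' @param aggregate_by Column averaged over before testing (default
#'   `"cell_id"`); `NULL` for none.
#' @param used_only If `TRUE` and a logical `used` column exists, drop
#'   unused rows first.
#' @return An object of class `comparison_table` with `groups` and
#'   `tests` data.frames.
#' @export
build_table <- function(records, value = "fwhm_nm", group = "group",
                        aggregate_by = "cell_id", used_only = TRUE) {
  stopifnot(is.data.frame(records), value %in% names(records),
            group %in% names(records))
  if (used_only && "used" %in% names(records)) {
    records <- records[records$used, , drop = FALSE]
  }
  records <- records[is.finite(records[[value]]), , drop = FALSE]
  if (!nrow(records)) stop("no usable records")
  smallest <- tapply(records[[value]], records[[group]], min)
  if (!is.null(aggregate_by) && aggregate_by %in% names(records)) {
    agg <- stats::aggregate(records[[value]],
                            by = list(group = records[[group]],
                                      unit = records[[aggregate_by]]),
                            FUN = mean)
    names(agg)[3] <- "value"
  } else {
    agg <- data.frame(group = records[[group]], unit = seq_len(nrow(records)),
                      value = records[[value]])
  }
  glev <- unique(as.character(agg$group))
  groups <- do.call(rbind, lapply(glev, function(g) {
    v <- agg$value[agg$group == g]
    data.frame(group = g, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v), smallest = unname(smallest[[g]]))
  }))
  tests <- NULL
  if (length(glev) >= 2) {
    pairs <- utils::combn(glev, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      pr <- pairs[, j]
      va <- agg$value[agg$group == pr[1]]
      vb <- agg$value[agg$group == pr[2]]
      if (length(va) < 2 || length(vb) < 2) {
        warning("group with < 2 units omitted from tests: ",
                pr[which.min(c(length(va), length(vb)))], call. = FALSE)
        return(NULL)
      }
      wt <- welch_t_test(va, vb)
      data.frame(group_a = pr[1], group_b = pr[2],
                 mean_a = mean(va), sd_a = stats::sd(va), n_a = length(va),
                 mean_b = mean(vb), sd_b = stats::sd(vb), n_b = length(vb),
                 t_stat = wt$t_stat, dof = wt$dof, p_value = wt$p_value,
                 stars = p_stars(wt$p_value))
    }))
  }
  structure(list(groups = groups, tests = tests, value = value),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, digits = 3, ...) {
  cat("Group summaries (", x$value, ", mean +/- SD, smallest = minimum measured value):\n",
      sep = "")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-28s %.*g +/- %.*g (n = %d), smallest %.*g\n",
                g$group[i], digits, g$mean[i], digits, g$sd[i], g$n[i],
                digits, g$smallest[i]))
  }
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("Pairwise Welch t-tests (two-sided, unequal variances):\n")
    t <- x$tests
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %s vs %s: t = %.*g, df = %.*g, p = %.3g %s\n",
                  t$group_a[i], t$group_b[i], digits, t$t_stat[i],
                  digits, t$dof[i], t$p_value[i], t$stars[i]))
    }
  }
  invisible(x)
}

#' Write a comparison table to CSV files
#'
#' @param x A [build_table()] result.
#' @param prefix File-path prefix; writes `<prefix>_groups.csv` and
#'   `<prefix>_tests.csv`.
#' @return The file paths, invisibly.
#' @export
write_comparison_table <- function(x, prefix) {
  stopifnot(inherits(x, "comparison_table"))
  pg <- paste0(prefix, "_groups.csv")
  utils::write.csv(x$groups, pg, row.names = FALSE)
  paths <- pg
  if (!is.null(x$tests)) {
    pt <- paste0(prefix, "_tests.csv")
    utils::write.csv(x$tests, pt, row.names = FALSE)
    paths <- c(paths, pt)
  }
  invisible(paths)
}
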