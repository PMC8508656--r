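# Pearson colocalization with Costes automatic thresholding, and
# dual-channel line-intensity profiles.

#' Pearson's correlation of two image channels
#'
#' Standard product-moment correlation over (optionally masked) pixels.
#' Unchanged under positive affine rescaling of either channel and
#' symmetric in channel order; +1 is perfect correlation, -1 perfect
#' anti-correlation.
#'
#' @param ch1,ch2 Numeric matrices of equal dimension.
#' @param mask Optional logical matrix selecting the analysis pixels.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(ch1, ch2, mask = NULL) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(ch1)))
    ch1 <- ch1[mask]; ch2 <- ch2[mask]
  }
  if (length(ch1) < 2) stop("need at least 2 pixels")
  if (stats::sd(ch1) == 0 || stats::sd(ch2) == 0) {
    stop("undefined correlation: constant channel on mask")
  }
  stats::cor(as.vector(ch1), as.vector(ch2))
}

# orthogonal (total least squares) regression of ch2 on ch1
tls_regression <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  cv <- stats::cov(cbind(x - mx, y - my))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (abs(v[1]) < 1e-15) stop("degenerate regression: vertical principal axis")
  a <- v[2] / v[1]
  list(slope = a, intercept = my - a * mx)
}

#' Costes automatic thresholds
#'
#' Fits the orthogonal (total least squares) regression `ch2 = a*ch1 + b`,
#' then scans the candidate threshold `T1` downward over the sorted unique
#' intensities of `ch1` with `T2 = a*T1 + b`, stopping at the first `T1`
#' for which the Pearson correlation of the pixels below both thresholds
#' is `<= 0` (no residual positive correlation in the "background"), is
#' undefined, or the below-set has fewer than 2 pixels.
#'
#' The scan is evaluated with an exactly equivalent vectorized
#' formulation: pixel `i` belongs to the below-set of `T1` iff
#' `max(ch1_i, (ch2_i - b)/a) < T1`, so sorting by that exit threshold
#' gives every candidate's below-set statistics from cumulative sums.
#'
#' @param ch1,ch2 Numeric matrices of equal dimension, nonconstant.
#' @param below `"both"` (default; pixels below both thresholds, the
#'   original formulation) or `"either"`.
#' @return List with `threshold_ch1`, `threshold_ch2` (`= a*T1 + b`
#'   exactly), `slope`, `intercept`, `pearson_below` (at termination;
#'   `NA` if the below-set was empty/degenerate) and `n_below`.
#' @export
costes_thresholds <- function(ch1, ch2, below = c("both", "either")) {
  below <- match.arg(below)
  stopifnot(identical(dim(ch1), dim(ch2)))
  x <- as.vector(ch1); y <- as.vector(ch2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant channel")
  reg <- tls_regression(x, y)
  a <- reg$slope; b <- reg$intercept
  if (a <= 0) {
    stop("Costes thresholds undefined: anti-correlated channels ",
         "(TLS slope <= 0); report the global Pearson coefficient instead")
  }
  # exit threshold: largest T1 for which pixel i is still below
  e <- if (below == "both") pmax(x, (y - b) / a) else pmin(x, (y - b) / a)
  ord <- order(e)
  xs <- x[ord]; ys <- y[ord]; es <- e[ord]
  cn <- seq_along(xs)
  sx <- cumsum(xs); sy <- cumsum(ys)
  sxx <- cumsum(xs^2); syy <- cumsum(ys^2); sxy <- cumsum(xs * ys)
  r_of <- function(n) {
    num <- n * sxy[n] - sx[n] * sy[n]
    den <- (n * sxx[n] - sx[n]^2) * (n * syy[n] - sy[n]^2)
    ifelse(den <= 0, NA_real_, num / sqrt(den))
  }
  cand <- sort(unique(x), decreasing = TRUE)
  for (T1 in cand) {
    n_bel <- findInterval(T1, es, left.open = TRUE)  # count of e_i < T1
    if (n_bel < 2) {
      return(costes_out(T1, a, b, NA_real_, n_bel))
    }
    r <- r_of(n_bel)
    if (is.na(r) || r <= 0) {
      return(costes_out(T1, a, b, r, n_bel))
    }
  }
  costes_out(cand[length(cand)], a, b, NA_real_, 0L)
}

costes_out <- function(T1, a, b, r, n) {
  list(threshold_ch1 = T1, threshold_ch2 = a * T1 + b,
       slope = a, intercept = b, pearson_below = r, n_below = as.integer(n))
}

#' Full Costes-thresholded colocalization report
#'
#' Computes the Costes thresholds, then Pearson's correlation over all
#' pixels (`pearson_global`), over the pixels above threshold in either
#' channel (`pearson_coloc`, the complement of the below-set), and over
#' the excluded below-set (`pearson_below`).  Nothing is rounded.
#'
#' @param ch1,ch2 Numeric matrices, or an [image_stack()] for `ch1` (its
#'   first two channels' middle slices are used, `ch2` ignored).
#' @param below Below-set convention, see [costes_thresholds()].
#'
#' @details When the orthogonal regression slope is not positive (channels
#'   uncorrelated or anti-correlated) Costes thresholds are undefined; the
#'   report then carries `NA` thresholds, sets `degenerate = TRUE`, and
#'   falls back to the global Pearson coefficient for `pearson_coloc` --
#'   the natural reading of "no positive correlation anywhere".
#' @return An object of class `costes_result` with fields `slope`,
#'   `intercept`, `threshold_ch1`, `threshold_ch2`, `pearson_global`,
#'   `pearson_coloc`, `pearson_below`, `n_pixels_used`, `n_pixels_total`.
#' @export
coloc_report <- function(ch1, ch2 = NULL, below = c("both", "either")) {
  below <- match.arg(below)
  if (inherits(ch1, "image_stack")) {
    stack <- ch1
    if (dim(stack$pixels)[1] < 2) stop("stack needs two channels")
    ch1 <- get_plane(stack, 1)
    ch2 <- get_plane(stack, 2)
  }
  stopifnot(is.matrix(ch1), is.matrix(ch2))
  th <- tryCatch(costes_thresholds(ch1, ch2, below = below),
                 error = function(e) {
                   if (grepl("anti-correlated", conditionMessage(e))) NULL
                   else stop(e)
                 })
  if (is.null(th)) {
    r_glob <- pearson_cc(ch1, ch2)
    return(structure(list(
      slope = NA_real_, intercept = NA_real_,
      threshold_ch1 = NA_real_, threshold_ch2 = NA_real_,
      pearson_global = r_glob, pearson_coloc = r_glob,
      pearson_below = NA_real_,
      n_pixels_used = length(ch1), n_pixels_total = length(ch1),
      below = below, degenerate = TRUE
    ), class = "costes_result"))
  }
  bel <- if (below == "both") {
    ch1 < th$threshold_ch1 & ch2 < th$threshold_ch2
  } else {
    ch1 < th$threshold_ch1 | ch2 < th$threshold_ch2
  }
  above <- !bel
  r_glob <- pearson_cc(ch1, ch2)
  r_col <- if (sum(above) >= 2 && stats::sd(ch1[above]) > 0 &&
               stats::sd(ch2[above]) > 0) {
    pearson_cc(ch1, ch2, mask = above)
  } else NA_real_
  structure(list(
    slope = th$slope, intercept = th$intercept,
    threshold_ch1 = th$threshold_ch1, threshold_ch2 = th$threshold_ch2,
    pearson_global = r_glob,
    pearson_coloc = r_col,
    pearson_below = th$pearson_below,
    n_pixels_used = sum(above),
    n_pixels_total = length(ch1),
    below = below, degenerate = FALSE
  ), class = "costes_result")
}

#' @export
print.costes_result <- function(x, ...) {
  cat("Costes-thresholded colocalization\n")
  cat(sprintf("  regression   : ch2 = %.4g * ch1 + %.4g (orthogonal)\n",
              x$slope, x$intercept))
  cat(sprintf("  thresholds   : T1 = %.4g, T2 = %.4g\n",
              x$threshold_ch1, x$threshold_ch2))
  cat(sprintf("  Pearson r    : global %.4f | coloc %.4f | below %s\n",
              x$pearson_global, x$pearson_coloc,
              ifelse(is.na(x$pearson_below), "NA",
                     sprintf("%.4f", x$pearson_below))))
  cat(sprintf("  pixels used  : %d of %d\n", x$n_pixels_used, x$n_pixels_total))
  invisible(x)
}

#' Dual-channel line-intensity profile
#'
#' Samples two channels along a straight line (ROI) by bilinear
#' interpolation at spacing `pixel_size/3` and normalizes each trace to
#' its own maximum, the standard presentation for comparing the lamin A
#' and lamin B1 intensity courses along the lamina.
#'
#' @param stack An [image_stack()] with at least two channels.
#' @param line Numeric `c(row1, col1, row2, col2)` endpoints in pixel
#'   coordinates.
#' @param channels Two channel names or indices (default first two).
#' @param z Slice (default middle).
#' @return An object of class `dual_profile`: a data.frame with
#'   `distance_nm`, `ch1_norm`, `ch2_norm` (each trace's maximum is
#'   exactly 1).
#' @export
dual_profile <- function(stack, line, channels = c(1, 2), z = NULL) {
  stopifnot(inherits(stack, "image_stack"), length(line) == 4)
  p1 <- get_plane(stack, channels[1], z)
  p2 <- get_plane(stack, channels[2], z)
  if (!all(in_bounds(p1, line[c(1, 3)], line[c(2, 4)]))) {
    stop("line endpoints outside image bounds")
  }
  len_px <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  spacing_nm <- stack$pixel_size_nm / 3
  n <- max(2L, floor(len_px * stack$pixel_size_nm / spacing_nm) + 1L)
  t <- seq(0, 1, length.out = n)
  r <- line[1] + t * (line[3] - line[1])
  cc <- line[2] + t * (line[4] - line[2])
  v1 <- bilinear_sample(p1, r, cc)
  v2 <- bilinear_sample(p2, r, cc)
  if (max(v1) <= 0 || max(v2) <= 0) stop("zero-maximum channel along line")
  out <- data.frame(distance_nm = t * len_px * stack$pixel_size_nm,
                    ch1_norm = v1 / max(v1),
                    ch2_norm = v2 / max(v2))
  class(out) <- c("dual_profile", "data.frame")
  attr(out, "channels") <- c(
    if (is.character(channels[1])) channels[1] else stack$channel_names[channels[1]],
    if (is.character(channels[2])) channels[2] else stack$channel_names[channels[2]])
  out
}

#' @export
plot.dual_profile <- function(x, ...) {
  chn <- attr(x, "channels")
  graphics::plot(x$distance_nm, x$ch1_norm, type = "l", col = "red3", lwd = 2,
                 ylim = c(0, 1), xlab = "distance (nm)",
                 ylab = "intensity (normalized to maximum)", ...)
  graphics::lines(x$distance_nm, x$ch2_norm, col = "forestgreen", lwd = 2)
  graphics::legend("topright", legend = chn, col = c("red3", "forestgreen"),
                   lwd = 2, bty = "n")
  invisible(x)
}
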