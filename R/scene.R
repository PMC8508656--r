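# Ground-truth generation for two-channel nuclear-lamina scenes.
#
# Two views are supported, matching how the lamina is actually imaged:
#   * mid_plane: optical section through the nuclear equator; the lamina is
#     a thin elliptical shell of known radial width, with a dimmer diffuse
#     nucleoplasmic component inside.  Used for thickness measurements.
#   * top: section at the upper nuclear surface; the lamina appears as a
#     filament meshwork.  Two channels share a configurable fraction of the
#     filament skeleton; the rest is channel-specific.  Used for
#     colocalization.
#
# Scenes are rendered on a supersampled grid (default 5 nm pitch) because
# the true shell width (~14 nm) is well below the detector pixel (~30 nm).

#' Scene configuration for the synthetic lamina simulator
#'
#' @param view `"mid_plane"` (equatorial section, elliptical shell) or
#'   `"top"` (surface section, filament meshwork).
#' @param nucleus_semi_axes_um Ellipse semi-axes (x, y) of the mid-plane
#'   nuclear outline, in micrometres.  The default is a scaled-down nucleus;
#'   rim thickness and colocalization measures are local and do not depend
#'   on overall nuclear size.
#' @param true_thickness_nm True lamina width (shell radial width, or
#'   filament width in the top view).  Default 14 nm, the thickness of the
#'   lamina as established by cryo-electron tomography.
#' @param mesh_density Filaments per square micrometre (top view).
#' @param mean_filament_um Mean filament segment length (top view).
#' @param shared_fraction Fraction \eqn{\rho \in [0,1]} of the filament
#'   skeleton common to both channels (top view).  In the mid-plane view the
#'   shell geometry is always shared.
#' @param radial_offset_nm Shift of the channel-B structure toward the
#'   nucleus exterior, in nm.  Literature values for the lamin B1 vs lamin
#'   A/C offset are ~15--20 nm.  In the top view this is applied as a
#'   uniform lateral translation of the channel-B skeleton (the physical
#'   offset is out of plane there; a lateral shift reproduces its
#'   decorrelating effect at the same magnitude).
#' @param nucleoplasm_level Relative intensity in `[0, 1)` of the diffuse
#'   interior (nucleoplasmic) lamin signal.
#' @param modulation_amplitude Relative amplitude of the smooth
#'   labeling-density modulation shared by both channels (default 0.4).
#'   Real lamina images show large-scale brightness variation over the
#'   shell (local lamin density, labeling efficiency); because the two
#'   channels stain the same shell this variation is common to both, and
#'   it is what keeps their correlation high once a wide PSF has averaged
#'   away the channel-specific fine structure.  Set 0 to disable.
#' @param modulation_scale_um Correlation length of that modulation.
#' @param supersample_nm Ground-truth raster pitch in nm (default 5).
#' @param field_um Side length of the square top-view field, in micrometres.
#' @param margin_um Clear margin around the mid-plane nucleus, in
#'   micrometres; must accommodate the PSF support plus profile sampling.
#' @return An object of class `scene_config`.
#' @seealso [build_lamina_scene()], [optics_config()]
#' @export
scene_config <- function(view = c("mid_plane", "top"),
                         nucleus_semi_axes_um = c(2.2, 1.7),
                         true_thickness_nm = 14,
                         mesh_density = 6,
                         mean_filament_um = 1.2,
                         shared_fraction = 0.5,
                         radial_offset_nm = 0,
                         nucleoplasm_level = 0.02,
                         modulation_amplitude = 0.4,
                         modulation_scale_um = 1,
                         supersample_nm = 5,
                         field_um = 5,
                         margin_um = 1.2) {
  view <- match.arg(view)
  stopifnot(length(nucleus_semi_axes_um) == 2, all(nucleus_semi_axes_um > 0),
            true_thickness_nm > 0,
            shared_fraction >= 0, shared_fraction <= 1,
            radial_offset_nm >= 0,
            nucleoplasm_level >= 0, nucleoplasm_level < 1,
            supersample_nm > 0, mesh_density > 0, mean_filament_um > 0,
            field_um > 0, margin_um >= 0,
            modulation_amplitude >= 0, modulation_scale_um > 0)
  structure(list(
    view = view,
    nucleus_semi_axes_um = as.numeric(nucleus_semi_axes_um),
    true_thickness_nm = true_thickness_nm,
    mesh_density = mesh_density,
    mean_filament_um = mean_filament_um,
    shared_fraction = shared_fraction,
    radial_offset_nm = radial_offset_nm,
    nucleoplasm_level = nucleoplasm_level,
    modulation_amplitude = modulation_amplitude,
    modulation_scale_um = modulation_scale_um,
    supersample_nm = supersample_nm,
    field_um = field_um,
    margin_um = margin_um
  ), class = "scene_config")
}

#' Optics configuration (effective PSF, detector, noise)
#'
#' @param modality `"confocal"` or `"sted"`.  Sets the default lateral PSF
#'   FWHM: 241 nm (confocal) or 60 nm (STED), the smallest measured line
#'   widths of the two modalities.
#' @param psf_fwhm_lateral_nm Lateral FWHM of the effective Gaussian PSF.
#' @param psf_fwhm_axial_nm Axial FWHM; only weights out-of-focus z-slices.
#' @param pixel_size_nm Detector pixel size (default 30 nm).
#' @param z_slices Number of z-slices (default 3).
#' @param z_step_nm Axial step between slices (default 100 nm).
#' @param photons_peak Expected photon count at the brightest lamina pixel.
#' @param read_noise_sd Gaussian read-noise SD in counts.
#' @param seed Integer seed for the rendering noise stream.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(modality = c("confocal", "sted"),
                          psf_fwhm_lateral_nm = NULL,
                          psf_fwhm_axial_nm = 600,
                          pixel_size_nm = 30,
                          z_slices = 3,
                          z_step_nm = 100,
                          photons_peak = 500,
                          read_noise_sd = 1,
                          seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(psf_fwhm_lateral_nm)) {
    psf_fwhm_lateral_nm <- switch(modality, confocal = 241, sted = 60)
  }
  stopifnot(psf_fwhm_lateral_nm > 0, psf_fwhm_axial_nm > 0,
            pixel_size_nm > 0, z_slices >= 1, z_step_nm > 0,
            photons_peak > 0, read_noise_sd >= 0)
  if (psf_fwhm_lateral_nm < 2 * pixel_size_nm) {
    warning("PSF FWHM (", psf_fwhm_lateral_nm, " nm) is below twice the pixel size (",
            pixel_size_nm, " nm): the image undersamples the PSF", call. = FALSE)
  }
  structure(list(
    modality = modality,
    psf_fwhm_lateral_nm = psf_fwhm_lateral_nm,
    psf_fwhm_axial_nm = psf_fwhm_axial_nm,
    pixel_size_nm = pixel_size_nm,
    z_slices = as.integer(z_slices),
    z_step_nm = z_step_nm,
    photons_peak = photons_peak,
    read_noise_sd = read_noise_sd,
    seed = as.integer(seed)
  ), class = "optics_config")
}

# grid size: even, divisible by 12 so detector binning factors 2,3,4,6,12 fit
scene_grid_n <- function(half_extent_nm, supersample_nm) {
  2L * 6L * as.integer(ceiling(half_extent_nm / (6 * supersample_nm)))
}

# centred coordinates (nm) of supersample cell centres for an n-cell axis
scene_axis_nm <- function(n, supersample_nm) {
  (seq_len(n) - (n + 1) / 2) * supersample_nm
}

#' Render the ground-truth scene
#'
#' Produces noiseless, supersampled intensity maps for both channels plus
#' the true rim geometry.  Deterministic given `(config, seed)`.
#'
#' In the mid-plane view each channel is an elliptical annulus of radial
#' width `true_thickness_nm` centred on the rim, over a uniform interior at
#' `nucleoplasm_level`; channel B is shifted outward by `radial_offset_nm`.
#' In the top view random straight filament segments of width
#' `true_thickness_nm` are rasterized; a fraction `shared_fraction` of
#' segments appears in both channels (channel B shifted by the offset), the
#' rest are drawn independently per channel from separate substreams so
#' changing `shared_fraction` does not reshuffle the shared filaments.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed for the scene's filament stream.
#' @return An object of class `ground_truth` with elements `channel_maps`
#'   (list of two supersampled matrices, rows = y, cols = x),
#'   `supersample_nm`, `true_thickness_nm`, `shared_fraction`,
#'   `radial_offset_nm`, `view`, and (mid-plane) `rim_polygon`, a matrix of
#'   rim centre-line coordinates in nm (columns `x`, `y`, origin at the grid
#'   centre).
#' @export
build_lamina_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  ss <- config$supersample_nm
  w <- config$true_thickness_nm
  if (w < ss) {
    stop("true_thickness_nm (", w, ") is below the supersample pitch (", ss,
         " nm); the shell cannot be represented")
  }
  if (config$view == "mid_plane") {
    gt <- scene_mid_plane(config)
  } else {
    gt <- scene_top(config, seed)
  }
  if (config$modulation_amplitude > 0) {
    d <- dim(gt$channel_maps[[1]])
    M <- pmax(1 + config$modulation_amplitude *
                smooth_field(d[1], d[2], config$supersample_nm,
                             config$modulation_scale_um * 1000,
                             seed + 3000003L), 0.1)
    gt$channel_maps <- lapply(gt$channel_maps, function(m) m * M)
  }
  gt$true_thickness_nm <- w
  gt$shared_fraction <- config$shared_fraction
  gt$radial_offset_nm <- config$radial_offset_nm
  gt$supersample_nm <- ss
  gt$view <- config$view
  gt$config <- config
  class(gt) <- "ground_truth"
  gt
}

# Mid-plane: elliptical shell via a first-order signed distance to the
# ellipse boundary (accurate near the rim, where the shell lives).
scene_mid_plane <- function(config) {
  ss <- config$supersample_nm
  a <- config$nucleus_semi_axes_um[1] * 1000
  b <- config$nucleus_semi_axes_um[2] * 1000
  w <- config$true_thickness_nm
  off <- config$radial_offset_nm
  nx <- scene_grid_n(a + config$margin_um * 1000, ss)
  ny <- scene_grid_n(b + config$margin_um * 1000, ss)
  x <- scene_axis_nm(nx, ss)
  y <- scene_axis_nm(ny, ss)
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)
  F <- sqrt((X / a)^2 + (Y / b)^2)
  gF <- sqrt(X^2 / a^4 + Y^2 / b^4) / pmax(F, 1e-12)
  d <- (F - 1) / pmax(gF, 1e-12)           # signed distance, + outside
  band <- function(dd) clamp01((w / 2 - abs(dd)) / ss + 0.5)
  interior <- function(dd) clamp01((-dd - w / 2) / ss + 0.5)
  lev <- config$nucleoplasm_level
  chA <- pmax(band(d), lev * interior(d))
  chB <- pmax(band(d - off), lev * interior(d - off))
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  rim <- cbind(x = a * cos(theta), y = b * sin(theta))
  list(channel_maps = list(chA, chB), rim_polygon = rim,
       axes_nm = list(x = x, y = y))
}

# unit-variance smooth Gaussian random field: coarse white noise at half
# the correlation scale, cubic-upsampled to the full grid
smooth_field <- function(ny, nx, ss_nm, scale_nm, seed) {
  sp <- scale_nm / 2
  my <- ceiling(ny * ss_nm / sp) + 3L
  mx <- ceiling(nx * ss_nm / sp) + 3L
  z <- with_seed(seed, matrix(stats::rnorm(my * mx), my, mx))
  ry <- seq(2, my - 1, length.out = ny)
  rx <- seq(2, mx - 1, length.out = nx)
  f <- matrix(cubic_sample(z, rep(ry, times = nx), rep(rx, each = ny)), ny, nx)
  (f - mean(f)) / stats::sd(f)
}

# rasterize one segment (soft-edged band of width w) into an accumulator
rasterize_segment <- function(acc, p1, p2, w, ss, x, y) {
  lo_x <- min(p1[1], p2[1]) - w; hi_x <- max(p1[1], p2[1]) + w
  lo_y <- min(p1[2], p2[2]) - w; hi_y <- max(p1[2], p2[2]) + w
  jx <- which(x >= lo_x & x <= hi_x)
  jy <- which(y >= lo_y & y <= hi_y)
  if (!length(jx) || !length(jy)) return(acc)
  X <- matrix(x[jx], length(jy), length(jx), byrow = TRUE)
  Y <- matrix(y[jy], length(jy), length(jx))
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 < 1e-9) return(acc)
  t <- ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / L2
  t <- pmin(pmax(t, 0), 1)
  dx <- X - (p1[1] + t * v[1])
  dy <- Y - (p1[2] + t * v[2])
  dist <- sqrt(dx^2 + dy^2)
  val <- clamp01((w / 2 - dist) / ss + 0.5)
  acc[jy, jx] <- pmax(acc[jy, jx], val)
  acc
}

draw_segments <- function(n, field_nm, mean_len_nm, seed) {
  # one block of four uniforms per segment, so the first k segments are
  # identical whatever n is (raising the shared fraction must only append
  # filaments, never reshuffle the existing ones)
  u <- with_seed(seed, matrix(stats::runif(4 * n), ncol = 4, byrow = TRUE))
  if (n == 0) return(list(cx = numeric(0), cy = numeric(0),
                          th = numeric(0), len = numeric(0)))
  list(cx = u[, 1] * field_nm,
       cy = u[, 2] * field_nm,
       th = u[, 3] * pi,
       len = (0.5 + u[, 4]) * mean_len_nm)
}

scene_top <- function(config, seed) {
  ss <- config$supersample_nm
  w <- config$true_thickness_nm
  field <- config$field_um * 1000
  n <- scene_grid_n(field / 2, ss)
  x <- scene_axis_nm(n, ss)
  y <- scene_axis_nm(n, ss)
  area <- (config$field_um)^2
  n_total <- max(1L, round(config$mesh_density * area))
  n_shared <- round(config$shared_fraction * n_total)
  n_unique <- n_total - n_shared
  half <- field / 2
  segs_shared <- draw_segments(n_shared, field, config$mean_filament_um * 1000,
                               seed)
  segs_a <- draw_segments(n_unique, field, config$mean_filament_um * 1000,
                          seed + 1000003L)
  segs_b <- draw_segments(n_unique, field, config$mean_filament_um * 1000,
                          seed + 2000003L)
  paint <- function(acc, segs, shift_x = 0) {
    if (!length(segs$cx)) return(acc)
    for (i in seq_along(segs$cx)) {
      dxy <- c(cos(segs$th[i]), sin(segs$th[i])) * segs$len[i] / 2
      ctr <- c(segs$cx[i] - half + shift_x, segs$cy[i] - half)
      acc <- rasterize_segment(acc, ctr - dxy, ctr + dxy, w, ss, x, y)
    }
    acc
  }
  chA <- matrix(0, n, n)
  chA <- paint(chA, segs_shared)
  chA <- paint(chA, segs_a)
  chB <- matrix(0, n, n)
  chB <- paint(chB, segs_shared, shift_x = config$radial_offset_nm)
  chB <- paint(chB, segs_b, shift_x = config$radial_offset_nm)
  lev <- config$nucleoplasm_level
  if (lev > 0) {
    chA <- pmax(chA, lev)
    chB <- pmax(chB, lev)
  }
  list(channel_maps = list(chA, chB), rim_polygon = NULL,
       axes_nm = list(x = x, y = y))
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$channel_maps[[1]])
  cat("ground_truth scene (", x$view, " view)\n", sep = "")
  cat("  supersampled maps : 2 channels, ", d[1], " x ", d[2], " at ",
      x$supersample_nm, " nm/cell\n", sep = "")
  cat("  true thickness    : ", x$true_thickness_nm, " nm\n", sep = "")
  cat("  shared fraction   : ", x$shared_fraction, "\n", sep = "")
  cat("  radial offset     : ", x$radial_offset_nm, " nm\n", sep = "")
  invisible(x)
}
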