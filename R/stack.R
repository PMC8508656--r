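# The multi-channel image container and its TIFF + sidecar-JSON I/O.

#' Multi-channel image stack
#'
#' The unit every pipeline stage consumes and produces: a
#' channel x z x y x x array of nonnegative pixel values with the pixel
#' size (nm) attached, since thickness in nm is meaningless without it.
#'
#' @param pixels 4D array `[channel, z, y, x]` (a 2D matrix is promoted to
#'   a single-channel, single-slice stack).
#' @param channel_names Character vector, one per channel.
#' @param pixel_size_nm Lateral pixel size in nm (> 0).
#' @param z_step_nm Axial step between slices in nm.
#' @param provenance Free-text description of where the pixels came from.
#' @param axes_nm Optional list with `x`, `y` pixel-centre coordinates in
#'   nm (attached by the simulator so measurements can be compared with
#'   ground truth).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, channel_names = NULL, pixel_size_nm,
                        z_step_nm = 100, provenance = "", axes_nm = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, 1L, nrow(pixels), ncol(pixels)))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 4,
            pixel_size_nm > 0, z_step_nm > 0)
  pixel_size_nm <- as.numeric(pixel_size_nm)
  z_step_nm <- as.numeric(z_step_nm)
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (any(pixels < 0)) stop("pixel values must be nonnegative")
  nc <- dim(pixels)[1]
  if (nc < 1) stop("at least one channel required")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  stopifnot(length(channel_names) == nc)
  structure(list(
    pixels = pixels,
    channel_names = as.character(channel_names),
    pixel_size_nm = pixel_size_nm,
    z_step_nm = z_step_nm,
    provenance = provenance,
    axes_nm = axes_nm
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat("image_stack: ", d[1], " channel(s) [", paste(x$channel_names, collapse = ", "),
      "], ", d[2], " z-slice(s), ", d[3], " x ", d[4], " px at ",
      x$pixel_size_nm, " nm/px\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Extract one image plane from a stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel index or name.
#' @param z Slice index; defaults to the middle slice, the in-focus plane
#'   analysed throughout (stacks are acquired as small z-stacks but
#'   measured on a single plane).
#' @return A numeric matrix (rows = y, cols = x).
#' @export
get_plane <- function(stack, channel = 1, z = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel)
    channel <- idx
  }
  if (is.null(z)) z <- (dim(stack$pixels)[2] + 1) %/% 2
  stack$pixels[channel, z, , ]
}

#' Write a stack to TIFF with a metadata sidecar
#'
#' Pages are written channel-major, then z.  Integer-valued stacks with a
#' maximum below 65536 are stored as 16-bit (bit-exact round trip);
#' anything else as 32-bit float.  Pixel size, z step, channel names,
#' encoding and provenance go into a JSON sidecar next to the TIFF.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param extra Optional named list merged into the sidecar (the simulator
#'   records its scene and optics parameters and ground-truth summary here).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- stack$pixels[ch, z, , ]
      k <- k + 1L
    }
  }
  vmax <- max(stack$pixels)
  int_ok <- vmax < 65535.5 && all(stack$pixels == round(stack$pixels))
  if (int_ok) {
    encoding <- "uint16"
    value_scale <- 65535
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    # TIFF values are stored in [0, 1]; rescale by the stack maximum
    encoding <- "float32"
    value_scale <- if (vmax > 0) vmax else 1
    tiff::writeTIFF(lapply(pages, function(p) p / value_scale), path,
                    bits.per.sample = 32L)
  }
  meta <- c(list(
    format = "laminq-stack",
    n_channel = d[1], n_z = d[2], ny = d[3], nx = d[4],
    channel_names = stack$channel_names,
    pixel_size_nm = stack$pixel_size_nm,
    z_step_nm = stack$z_step_nm,
    encoding = encoding,
    value_scale = value_scale,
    provenance = stack$provenance
  ), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a stack from TIFF
#'
#' Reads a TIFF written by [write_stack()] (using its JSON sidecar for the
#' axis layout and pixel size) or a plain single/multi-page TIFF, in which
#' case `pixel_size_nm` must be supplied and pages are treated as one
#' channel per page.  An explicit `pixel_size_nm` always takes precedence
#' over sidecar metadata.
#'
#' @param path TIFF path.
#' @param pixel_size_nm Pixel size override in nm.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  if (is.null(meta) && is.null(pixel_size_nm)) {
    stop("no pixel size: supply pixel_size_nm or provide a metadata sidecar (",
         sc, ")")
  }
  if (!is.null(meta) && identical(meta$format, "laminq-stack")) {
    ncn <- meta$n_channel; nz <- meta$n_z
    if (identical(meta$encoding, "uint16")) {
      pages <- lapply(pages, function(p) round(p * 65535))
    } else if (!is.null(meta$value_scale)) {
      pages <- lapply(pages, function(p) p * meta$value_scale)
    }
    pix <- array(0, dim = c(ncn, nz, nrow(pages[[1]]), ncol(pages[[1]])))
    k <- 1L
    for (ch in seq_len(ncn)) {
      for (z in seq_len(nz)) {
        pix[ch, z, , ] <- pages[[k]]
        k <- k + 1L
      }
    }
    image_stack(pix,
                channel_names = meta$channel_names,
                pixel_size_nm = if (!is.null(pixel_size_nm)) pixel_size_nm else meta$pixel_size_nm,
                z_step_nm = meta$z_step_nm,
                provenance = if (is.null(meta$provenance)) path else meta$provenance)
  } else {
    pix <- array(0, dim = c(length(pages), 1L, nrow(pages[[1]]), ncol(pages[[1]])))
    for (ch in seq_along(pages)) pix[ch, 1, , ] <- pages[[ch]]
    image_stack(pix, pixel_size_nm = pixel_size_nm, provenance = path)
  }
}

#' Simulate a lamina scene and write it to disk
#'
#' Convenience wrapper: builds the ground truth, renders it, and writes
#' the TIFF plus a sidecar JSON containing the full scene and optics
#' configuration and a ground-truth summary (true thickness, shared
#' fraction, radial offset, and the noiseless rendered-channel Pearson
#' correlation).
#'
#' @inheritParams render_image
#' @param config A [scene_config()].
#' @param path Output TIFF path.
#' @param scene_seed Seed for the scene geometry.
#' @return The [image_stack()], invisibly.
#' @export
simulate_lamina_images <- function(config, optics, path, scene_seed = 1L,
                                   noiseless = FALSE) {
  gt <- build_lamina_scene(config, seed = scene_seed)
  st <- render_image(gt, optics, noiseless = noiseless)
  truth <- list(true_thickness_nm = gt$true_thickness_nm,
                shared_fraction = gt$shared_fraction,
                radial_offset_nm = gt$radial_offset_nm,
                true_pearson = true_pearson(gt, optics))
  write_stack(st, path, extra = list(
    scene_config = unclass(config),
    optics_config = unclass(optics),
    scene_seed = scene_seed,
    ground_truth = truth))
  invisible(st)
}
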