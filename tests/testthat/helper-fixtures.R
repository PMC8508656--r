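# Small scene/optics fixtures so unit tests stay fast; acceptance tests use
# the package defaults (the study conditions).

tiny_mid_config <- function(...) {
  scene_config("mid_plane", nucleus_semi_axes_um = c(1.2, 0.9),
               margin_um = 0.8, ...)
}

tiny_top_config <- function(...) {
  scene_config("top", field_um = 2, ...)
}

sted_optics <- function(seed = 1L, ...) optics_config("sted", seed = seed, ...)
confocal_optics <- function(seed = 1L, ...) optics_config("confocal", seed = seed, ...)

# map ground-truth nm coordinates to pixel (row, col) coordinates of a
# simulated stack (uses the axes the simulator attaches)
gt_nm_to_px <- function(stack, xy_nm) {
  cbind(row = (xy_nm[, "y"] - stack$axes_nm$y[1]) / stack$pixel_size_nm + 1,
        col = (xy_nm[, "x"] - stack$axes_nm$x[1]) / stack$pixel_size_nm + 1)
}
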