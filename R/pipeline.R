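# End-to-end pipeline: (optionally simulated) images -> optional
# deconvolution -> thickness at the mid-plane -> colocalization at the
# top of the nucleus -> comparison tables.  Deterministic given the
# config seed; every stage's CSV is persisted with a stable header.

pipeline_allowed_keys <- c(
  "seed", "out_dir", "simulate", "n_cells", "modalities", "true_thickness_nm",
  "shared_fraction", "radial_offset_nm", "deconvolve", "deconv_max_iter",
  "thickness_positions", "inputs", "channels", "pixel_size_nm")

#' Pipeline configuration
#'
#' Validated before any stage runs; unknown keys are rejected.
#'
#' @param seed Master seed; every random stream in the run derives from it.
#' @param out_dir Output directory for images, CSVs and the run log.
#' @param simulate If `TRUE` (default) a simulated dataset is generated;
#'   otherwise `inputs` must list TIFF files readable by [read_stack()].
#' @param n_cells Simulated cells per modality.
#' @param modalities Character vector among `"confocal"`, `"sted"`.
#' @param true_thickness_nm,shared_fraction,radial_offset_nm Scene
#'   parameters for the simulated dataset.
#' @param deconvolve Apply Richardson-Lucy before measuring (default
#'   `FALSE`; every property of the measurements holds with and without).
#' @param deconv_max_iter Iteration cap when deconvolving.
#' @param thickness_positions Profiles per cell (default 5).
#' @param inputs Named list of input files when `simulate = FALSE`:
#'   `mid` and `top` character vectors of TIFF paths.
#' @param channels Channel-name pair used for colocalization.
#' @param pixel_size_nm Pixel-size override for plain-TIFF inputs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "laminq-report",
                            simulate = TRUE, n_cells = 3L,
                            modalities = c("confocal", "sted"),
                            true_thickness_nm = 14, shared_fraction = 0.5,
                            radial_offset_nm = 0,
                            deconvolve = FALSE, deconv_max_iter = 40L,
                            thickness_positions = 5L,
                            inputs = NULL, channels = c("laminA", "laminB1"),
                            pixel_size_nm = NULL) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              simulate = isTRUE(simulate), n_cells = as.integer(n_cells),
              modalities = match.arg(modalities, several.ok = TRUE),
              true_thickness_nm = true_thickness_nm,
              shared_fraction = shared_fraction,
              radial_offset_nm = radial_offset_nm,
              deconvolve = isTRUE(deconvolve),
              deconv_max_iter = as.integer(deconv_max_iter),
              thickness_positions = as.integer(thickness_positions),
              inputs = inputs, channels = channels,
              pixel_size_nm = pixel_size_nm)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_allowed_keys)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  stopifnot(cfg$n_cells >= 1, cfg$thickness_positions >= 1,
            cfg$shared_fraction >= 0, cfg$shared_fraction <= 1,
            cfg$true_thickness_nm > 0)
  if (!cfg$simulate && is.null(cfg$inputs)) {
    stop("simulate = FALSE requires 'inputs'")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON")
  do.call(pipeline_config, raw)
}

#' Run the full measurement pipeline
#'
#' Stages: dataset (simulated or read from `inputs`), optional
#' Richardson-Lucy deconvolution, per-cell thickness at the mid-plane,
#' Costes/Pearson colocalization at the top of the nucleus (mid-plane
#' images are not used for colocalization), and comparison tables.
#' Writes `thickness.csv`, `coloc.csv`, the group/test tables, the
#' serialized config and a log with the config hash, into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the tables are also returned
#'   as attributes `thickness_table` and `coloc_table` when computable.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "images"), showWarnings = FALSE)
  log_lines <- c(
    paste0("laminq ", as.character(utils::packageVersion("laminq")),
           " | R ", R.version.string),
    paste0("seed: ", config$seed))

  mids <- list(); tops <- list()
  if (config$simulate) {
    for (mod in config$modalities) {
      for (i in seq_len(config$n_cells)) {
        sseed <- config$seed + 977L * i
        sc_mid <- scene_config("mid_plane",
                               true_thickness_nm = config$true_thickness_nm,
                               radial_offset_nm = config$radial_offset_nm,
                               shared_fraction = config$shared_fraction)
        sc_top <- scene_config("top",
                               true_thickness_nm = config$true_thickness_nm,
                               radial_offset_nm = config$radial_offset_nm,
                               shared_fraction = config$shared_fraction)
        opt <- optics_config(mod, seed = config$seed + 7919L * i +
                               113L * match(mod, config$modalities))
        fm <- file.path(out, "images", sprintf("mid_%s_cell%02d.tif", mod, i))
        ft <- file.path(out, "images", sprintf("top_%s_cell%02d.tif", mod, i))
        simulate_lamina_images(sc_mid, opt, fm, scene_seed = sseed)
        simulate_lamina_images(sc_top, opt, ft, scene_seed = sseed)
        mids[[length(mids) + 1]] <- list(path = fm, modality = mod,
                                         cell = sprintf("cell%02d", i))
        tops[[length(tops) + 1]] <- list(path = ft, modality = mod,
                                         cell = sprintf("cell%02d", i))
      }
    }
  } else {
    for (p in config$inputs$mid) {
      mids[[length(mids) + 1]] <- list(path = p, modality = NA_character_,
                                       cell = tools::file_path_sans_ext(basename(p)))
    }
    for (p in config$inputs$top) {
      tops[[length(tops) + 1]] <- list(path = p, modality = NA_character_,
                                       cell = tools::file_path_sans_ext(basename(p)))
    }
  }

  load_stack <- function(path) {
    st <- read_stack(path, pixel_size_nm = config$pixel_size_nm)
    if (config$deconvolve) {
      psf <- NA_real_
      meta <- tryCatch(jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE),
                       error = function(e) NULL)
      if (!is.null(meta$optics_config$psf_fwhm_lateral_nm)) {
        psf <- meta$optics_config$psf_fwhm_lateral_nm
      }
      if (is.na(psf)) psf <- 241
      st <- deconvolve_stack(st, psf_fwhm_nm = psf,
                             max_iterations = config$deconv_max_iter)
    }
    st
  }

  # --- thickness on mid-plane images ------------------------------------
  th_rows <- NULL
  for (item in mids) {
    st <- load_stack(item$path)
    psf_guess <- switch(item$modality, confocal = 241, sted = 60, 300)
    for (ch in intersect(config$channels, st$channel_names)) {
      res <- tryCatch(
        measure_thickness(st, channel = ch,
                          n_positions = config$thickness_positions,
                          expected_fwhm_nm = psf_guess,
                          cell_id = item$cell, modality = item$modality),
        error = function(e) {
          log_lines <<- c(log_lines, paste0("thickness skipped (", item$path,
                                            ", ", ch, "): ", conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) th_rows <- rbind(th_rows, thickness_records(res))
    }
  }
  if (!is.null(th_rows)) {
    utils::write.csv(th_rows, file.path(out, "thickness.csv"), row.names = FALSE)
  }

  # --- colocalization on top-of-nucleus images --------------------------
  co_rows <- NULL
  for (item in tops) {
    st <- load_stack(item$path)
    rep <- tryCatch(coloc_report(st), error = function(e) {
      log_lines <<- c(log_lines, paste0("coloc skipped (", item$path, "): ",
                                        conditionMessage(e)))
      NULL
    })
    if (!is.null(rep)) {
      co_rows <- rbind(co_rows, data.frame(
        cell_id = item$cell, modality = item$modality,
        pearson_coloc = rep$pearson_coloc,
        pearson_global = rep$pearson_global,
        threshold_ch1 = rep$threshold_ch1, threshold_ch2 = rep$threshold_ch2,
        slope = rep$slope, intercept = rep$intercept,
        n_pixels_used = rep$n_pixels_used))
    }
  }
  if (!is.null(co_rows)) {
    utils::write.csv(co_rows, file.path(out, "coloc.csv"), row.names = FALSE)
  }

  # --- tables -----------------------------------------------------------
  th_tab <- co_tab <- NULL
  if (!is.null(th_rows) && length(unique(stats::na.omit(th_rows$modality))) >= 1) {
    th_rows$group <- paste(th_rows$modality, th_rows$channel, sep = "/")
    th_tab <- build_table(th_rows, value = "fwhm_nm", group = "group")
    write_comparison_table(th_tab, file.path(out, "thickness_table"))
  }
  if (!is.null(co_rows) && any(!is.na(co_rows$modality))) {
    co_rows$group <- co_rows$modality
    co_tab <- build_table(co_rows, value = "pearson_coloc", group = "group",
                          aggregate_by = "cell_id")
    write_comparison_table(co_tab, file.path(out, "coloc_table"))
  }

  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log_lines <- c(log_lines, paste0("config md5: ", unname(tools::md5sum(cfg_path))))
  writeLines(log_lines, file.path(out, "run.log"))
  res <- structure(out, thickness_table = th_tab, coloc_table = co_tab)
  invisible(res)
}
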