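#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults; any element
#' can be overridden via `...` or by a YAML file passed to [run_pipeline()].
#'
#' @param ... Named overrides.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    synth_preset = "drought-tray",    # or NULL when reading cubes from disk
    leaf_deficit = 0,
    reflectance_path = NULL, fluorescence_path = NULL,
    roi_file = NULL,
    spectral_factor = 3L, cross_track_factor = 4L,
    panel_region = NULL, panel_nominal_percent = 100,
    band_pair = NULL,                 # c(lambda1, lambda2) override
    register_axis = "x", max_shift = 20L,
    filter_band_nm = 815, filter_window = 3L,
    filter_frac_threshold = 0.10, filter_k_sd = 3,
    classifier_family = "discriminant", folds = 5L, repeats = 10L,
    timestamps = FALSE,
    out_dir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full monitoring pipeline
#'
#' Chains the processing stages end to end: scene input (synthetic phantom
#' pair or BIL cubes from disk), spectral/spatial binning, flat-field
#' reflectance conversion, band-ratio segmentation with Otsu masking,
#' fluorescence registration, masked spectral summaries and the
#' average-window filter, and (when both treatments are present)
#' cross-validated classification. All intermediate artifacts are written
#' under `out_dir` along with a machine-readable run manifest.
#'
#' @param config Configuration list from [default_config()], or a path to a
#'   YAML file with the same keys.
#' @return List with the stage outputs and the manifest (invisibly written
#'   to `out_dir` when set).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    cfg <- default_config()
    over <- yaml::read_yaml(config)
    cfg[names(over)] <- over
    config <- cfg
  }
  out_dir <- config$out_dir
  save_artifacts <- !is.null(out_dir)
  if (save_artifacts) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- if (isTRUE(config$timestamps))
    format(Sys.time(), "_%Y%m%d-%H%M%S") else ""
  manifest <- list(package_version = as.character(utils::packageVersion("hyperleaf")),
                   seed = config$seed, parameters = config, stages = list())
  done <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(status = "completed"), list(...))
  }
  stage <- "input"
  result <- list()
  tryCatch({
    # ---- input -------------------------------------------------------------
    if (!is.null(config$synth_preset)) {
      scenes <- switch(
        config$synth_preset,
        "drought-tray" = list(
          control = render_scene(drought_tray_spec("control",
                                                   seed = config$seed), raw = TRUE),
          drought = render_scene(drought_tray_spec("drought",
                                                   seed = config$seed + 1L,
                                                   leaf_deficit = config$leaf_deficit),
                                 raw = TRUE)),
        "single-pot" = list(
          control = render_scene(phantom_spec(seed = config$seed), raw = TRUE)),
        stop("unknown synth preset: ", config$synth_preset))
      raw_cubes <- lapply(scenes, `[[`, "raw_reflectance")
      panel_region <- scenes[[1L]]$panel_region
    } else {
      if (is.null(config$reflectance_path)) stop("no input cubes configured")
      raw_cubes <- list(scene = read_bil(config$reflectance_path))
      scenes <- NULL
      panel_region <- config$panel_region
      if (is.null(panel_region)) stop("panel_region required for disk input")
    }
    done("input", scenes = names(raw_cubes))

    # ---- bin + flat-field --------------------------------------------------
    stage <- "preprocess"
    refl <- lapply(raw_cubes, function(cb) {
      binned <- bin_cube(cb, config$spectral_factor, config$cross_track_factor)
      reg <- panel_region
      reg$x <- pmax(1L, reg$x %/% config$cross_track_factor)
      ref <- extract_panel_reference(binned, reg,
                                     nominal_percent = config$panel_nominal_percent)
      flat_field_correct(binned, ref)
    })
    done("preprocess", binned_dim = dim(refl[[1L]]$data))

    # ---- segmentation ------------------------------------------------------
    stage <- "segment"
    if (!is.null(config$roi_file)) {
      if (!file.exists(config$roi_file))
        stop("ROI file not found: ", config$roi_file)
      ls1 <- select_roi_spectra(refl[[1L]], read_roi(config$roi_file))
    } else if (!is.null(scenes)) {
      ls1 <- truth_roi_spectra(refl[[1L]], scenes[[1L]]$truth,
                               seed = config$seed)
    } else stop("ROI file required for disk input")
    if (is.null(config$band_pair)) {
      brs <- band_ratio_search(ls1)
      pair <- brs$best_pair
      polarity <- if (brs$best_r < 0) "above" else "below"
      result$band_ratio_search <- brs
    } else {
      pair <- config$band_pair
      polarity <- "above"
    }
    masks <- lapply(refl, function(cb)
      otsu_mask(ratio_image(cb, pair[1L], pair[2L]), polarity = polarity,
                provenance = list(lambda1 = pair[1L], lambda2 = pair[2L])))
    done("segment", lambda1 = unname(pair[1L]), lambda2 = unname(pair[2L]),
         polarity = polarity)

    # ---- registration ------------------------------------------------------
    stage <- "register"
    registration <- NULL
    if (!is.null(scenes)) {
      fl_binned <- lapply(scenes, function(sc) sc$fluorescence)
      registration <- lapply(names(refl), function(nm)
        register_pair(refl[[nm]], fl_binned[[nm]],
                      max_shift = config$max_shift,
                      axis = config$register_axis))
      names(registration) <- names(refl)
      done("register", shifts = lapply(registration,
                                       function(r) r$result$shift))
    } else done("register", skipped = "no fluorescence cube")

    # ---- features ----------------------------------------------------------
    stage <- "features"
    summaries <- mapply(function(cb, mk) summarize_spectra(cb, mk),
                        refl, masks, SIMPLIFY = FALSE)
    wfs <- mapply(function(cb, mk)
      window_filter(cb, mk, band_nm = config$filter_band_nm,
                    window = config$filter_window,
                    frac_threshold = config$filter_frac_threshold,
                    k_sd = config$filter_k_sd),
      refl, masks, SIMPLIFY = FALSE)
    areas <- leaf_area(masks, day = NA_integer_,
                       tray = seq_along(masks),
                       treatment = names(masks))
    done("features",
         retained_windows = vapply(wfs, function(w) w$counts$n_kept,
                                   integer(1)))

    # ---- classification ----------------------------------------------------
    stage <- "classify"
    report <- NULL
    if (length(wfs) >= 2L) {
      ds <- build_dataset(wfs, labels = names(wfs))
      report <- run_cv(ds, config$classifier_family, folds = config$folds,
                       repeats = config$repeats, seed = config$seed)
      done("classify", family = report$family,
           overall_accuracy = report$overall_accuracy, auc = report$auc)
    } else done("classify", skipped = "single treatment")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  result <- c(result, list(reflectance = refl, masks = masks,
                           registration = registration,
                           summaries = summaries, window_filters = wfs,
                           leaf_area = areas, cv_report = report))
  if (save_artifacts) {
    for (nm in names(masks))
      write_mask_png(masks[[nm]], file.path(out_dir,
                                            paste0("mask_", nm, stamp, ".png")))
    for (nm in names(summaries))
      utils::write.csv(summaries[[nm]]$table,
                       file.path(out_dir, paste0("spectra_", nm, stamp, ".csv")),
                       row.names = FALSE)
    utils::write.csv(areas, file.path(out_dir, paste0("leaf_area", stamp, ".csv")),
                     row.names = FALSE)
    if (!is.null(result$band_ratio_search))
      utils::write.csv(result$band_ratio_search$correlation_surface,
                       file.path(out_dir, paste0("correlation_surface", stamp,
                                                 ".csv")))
    if (!is.null(report))
      write_json_file(list(family = report$family,
                           overall_accuracy = report$overall_accuracy,
                           auc = report$auc,
                           confusion = as.vector(report$confusion),
                           repeat_accuracies = report$repeat_accuracies),
                      file.path(out_dir, paste0("cv_report", stamp, ".json")))
    manifest$artifact_checksums <-
      as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                       pattern = "\\.(csv|json|png)$")))
    write_json_file(manifest, file.path(out_dir, "manifest.json"))
  }
  result$manifest <- manifest
  invisible(result)
}
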