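# Small deterministic fixtures built in code.

# A tiny hypercube with reproducible random contents.
tiny_cube <- function(lines = 6L, samples = 8L, bands = 5L, seed = 1L,
                      modality = "raw") {
  set.seed(seed)
  hypercube(array(runif(lines * samples * bands, 0, 100),
                  dim = c(lines, samples, bands)),
            wavelengths = seq(500, by = 10, length.out = bands),
            modality = modality)
}

# Memoised phantom scenes: rendering is the slow part of the suite, so each
# (kind, seed) pair is rendered once per test run.
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(kind = c("single", "control", "drought"), seed = 2L,
                         ...) {
  kind <- match.arg(kind)
  key <- paste(kind, seed, sep = "_")
  if (is.null(.scene_cache[[key]])) {
    spec <- switch(kind,
                   single = phantom_spec(seed = seed, ...),
                   control = drought_tray_spec("control", seed = seed, ...),
                   drought = drought_tray_spec("drought", seed = seed, ...))
    .scene_cache[[key]] <- render_scene(spec)
  }
  .scene_cache[[key]]
}

# Labeled spectra pooled over several scan days, one tray per treatment per
# day — the weekly pooling used for the stress band-ratio analysis.
pooled_week_spectra <- function(base_seed = 1L, days = 5L, n = 200L) {
  sp <- NULL; lab <- integer(0); wl <- NULL
  for (d in seq_len(days) - 1L) {
    scc <- cached_scene("control", seed = base_seed + 7L * d)
    scd <- cached_scene("drought", seed = base_seed + 7L * d + 1000L)
    lc <- truth_roi_spectra(scc$reflectance, scc$truth, classes = "leaf",
                            n = n, seed = base_seed + d)
    ld <- truth_roi_spectra(scd$reflectance, scd$truth, classes = "leaf",
                            n = n, seed = base_seed + d + 50L)
    sp <- rbind(sp, lc$spectra, ld$spectra)
    lab <- c(lab, rep(1L, nrow(lc$spectra)), rep(2L, nrow(ld$spectra)))
    wl <- lc$wavelengths
  }
  labeled_spectra(sp, lab, wl)
}

# Window-filtered classification dataset from one control and one drought
# tray scene.
tray_dataset <- function(seed = 1L) {
  scc <- cached_scene("control", seed = seed)
  scd <- cached_scene("drought", seed = seed + 1000L)
  mk <- function(sc) otsu_mask(ratio_image(sc$reflectance, 559, 678), "above")
  wfs <- list(window_filter(scc$reflectance, mk(scc)),
              window_filter(scd$reflectance, mk(scd)))
  build_dataset(wfs, c("control", "drought"))
}

# Index of the band nearest a wavelength, on the reduced grid.
band_index <- function(nm, wl = reduced_wavelengths()) which.min(abs(wl - nm))
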