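#' Reduced-band wavelength grid of the instrument
#'
#' Band centers obtained by 3-pixel spectral averaging of the 300 collected
#' detector pixels (408-1001 nm at 1.98 nm): 100 bands at a 5.94 nm interval.
#'
#' @param cal A `spectral_calibration` (default the shipped preset).
#' @param spectral_factor Averaging factor (default 3).
#' @return Numeric vector of band centers in nm.
#' @export
reduced_wavelengths <- function(cal = calibration_preset(),
                                spectral_factor = 3L) {
  wl <- calibration_wavelengths(cal)
  nb <- length(wl) %/% spectral_factor
  colMeans(matrix(wl[seq_len(nb * spectral_factor)], nrow = spectral_factor))
}

logistic <- function(x) 1 / (1 + exp(-x))
gauss <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))

#' Parametric vegetation reflectance spectrum
#'
#' Smooth leaf endmember (reflectance fraction, 0-1) with the canonical VNIR
#' features: a green reflectance peak near 559 nm, the chlorophyll-a
#' absorption minimum at 672 nm, the red edge rising to a near-infrared
#' plateau around 815 nm, and strong blue absorption. The chlorophyll level
#' scales all pigment absorption, so the spectrum flattens toward the bare
#' background as the level approaches zero.
#'
#' @param chlorophyll Level in (0, 1]; default 0.8.
#' @param wavelengths Band centers in nm.
#' @param band_shift Shift of the chlorophyll-a absorption center in nm
#'   (default 0); small per-pixel shifts model pigment-composition
#'   variability.
#' @param green_shift Shift of the green reflectance peak in nm (default 0),
#'   modeling independent carotenoid/chlorophyll ratio variability.
#' @param chlb_amp Extra chlorophyll-b shoulder absorption at 650 nm
#'   (default 0); varies pixel to pixel with the chlorophyll a/b ratio.
#' @param car_amp Extra carotenoid absorption at 480 nm (default 0).
#' @return Reflectance fraction vector (values in (0, 1)).
#' @export
vegetation_spectrum <- function(chlorophyll = 0.8,
                                wavelengths = reduced_wavelengths(),
                                band_shift = 0, green_shift = 0,
                                chlb_amp = 0, car_amp = 0) {
  if (length(wavelengths) == 0L) stop("empty band grid")
  if (chlorophyll <= 0 || chlorophyll > 1)
    stop("chlorophyll level must be in (0, 1]")
  wl <- wavelengths
  # pigment-free background: flat with a gentle NIR maximum near 815 nm
  base <- 0.52 + 0.06 * gauss(wl, 815, 120)
  # absorption switched off across the red edge (~720 nm) into the NIR
  vis <- 1 - logistic((wl - 720) / 10)
  absorption <- 0.32 * gauss(wl, 672 + band_shift, 11) + # chlorophyll-a red band
    0.30 * gauss(wl, 445, 35) +               # blue band
    chlb_amp * gauss(wl, 650, 12) +           # chlorophyll-b shoulder
    car_amp * gauss(wl, 480, 30) +            # carotenoid band
    0.27 -                                    # broadband pigment losses
    0.16 * gauss(wl, 559 + green_shift, 20)   # green relief (the green peak)
  refl <- base - chlorophyll * vis * absorption
  pmax(refl, 0.01)
}

#' Parametric soil reflectance spectrum
#'
#' Featureless, slowly rising endmember typical of moist potting substrate.
#'
#' @param wavelengths Band centers in nm.
#' @param brightness Reflectance offset (fraction).
#' @param slope Total reflectance rise across 408-1001 nm.
#' @return Reflectance fraction vector.
#' @export
soil_spectrum <- function(wavelengths = reduced_wavelengths(),
                          brightness = 0.12, slope = 0.22) {
  brightness + slope * (wavelengths - 408) / 593
}

#' Chlorophyll fluorescence emission spectrum
#'
#' Sum of four Gaussian emission peaks: the dominant chlorophyll red peaks at
#' 690 and 732 nm, plus weak broad blue and green peaks near 450 and 530 nm
#' from phenolic leaf compounds.
#'
#' @param wavelengths Band centers in nm; the grid must span 440-740 nm.
#' @param amplitudes Named numeric: `blue`, `green`, `red690`, `red732`
#'   relative amplitudes. The defaults keep the blue/green peaks below 25%
#'   of the 690 nm peak.
#' @return Emission intensity vector (arbitrary units).
#' @export
fluorescence_spectrum <- function(wavelengths = reduced_wavelengths(),
                                  amplitudes = c(blue = 0.15, green = 0.20,
                                                 red690 = 1.0, red732 = 0.8)) {
  if (min(wavelengths) > 440 || max(wavelengths) < 740)
    stop("band grid must span 440-740 nm")
  wl <- wavelengths
  amplitudes["blue"] * gauss(wl, 450, 25) +
    amplitudes["green"] * gauss(wl, 530, 30) +
    amplitudes["red690"] * gauss(wl, 690, 12) +
    amplitudes["red732"] * gauss(wl, 732, 18)
}

#' Specification of a synthetic phantom scene
#'
#' Describes a lettuce-on-soil scene as imaged by the line-scan system: a
#' reference-panel strip at the scan origin, a tray of potted plants in a
#' rows x cols array, per-pot treatment (control/drought), and the imaging
#' noise model. Dimensions are in reduced-cube pixels (1 mm/pixel scale).
#'
#' Defaults encode the pilot drought study conditions: 2x3 pot trays, a
#' x1.15 drought reflectance plateau over 685-700 nm, 3% multiplicative
#' pixel noise, 0.4 percent-reflectance additive detector noise, per-pixel
#' chlorophyll jitter SD 0.005, leaf structural NIR variability SD 0.15
#' (leaf stacking/angle), soil color-slope jitter SD 0.12 with
#' partial-volume leaf contamination of soil pixels near the rosette
#' margin, and a 10-pixel leftward fluorescence shift.
#'
#' @param lines,samples Scene size in reduced pixels.
#' @param wavelengths Band grid (default 100 bands, 408-1001 nm at 5.94 nm).
#' @param pot_rows,pot_cols Tray layout (default 2 x 3).
#' @param pot_size Pot edge length in pixels.
#' @param leaf_radius Rosette radius in pixels.
#' @param panel_lines Number of leading scan lines covered by the panel
#'   strip.
#' @param treatment Per-pot treatment, `"control"` or `"drought"` (recycled).
#' @param drought_effect Multiplier (>= 1) on leaf reflectance over the
#'   685-700 nm plateau for drought pots.
#' @param leaf_deficit Fractional leaf-area deficit of drought pots
#'   (default 0; e.g. 0.29 for late-stage stress).
#' @param chlorophyll Mean chlorophyll level of the leaves.
#' @param chlorophyll_sd Per-pixel chlorophyll jitter SD.
#' @param nir_structure_sd SD of per-pixel leaf NIR scattering variability
#'   (leaf stacking and angle), applied beyond the red edge.
#' @param soil_slope_sd SD of the soil color-slope jitter.
#' @param mult_noise_sd SD of the per-pixel multiplicative lognormal noise.
#' @param add_noise_sd SD of additive detector noise, in percent-reflectance
#'   units.
#' @param pot_chl_sd,pot_nir_sd,pot_gain_sd,pot_band_shift_sd Pot-level
#'   random effects (shared by all leaf pixels of one pot): chlorophyll
#'   offset, NIR structure offset, lognormal brightness gain, pigment
#'   band-position offset in nm. These model plant-to-plant variability.
#' @param pot_response_sd Lognormal SD of each drought pot's stress
#'   response: the pot's log drought effect is
#'   `log(drought_effect) * exp(N(0, pot_response_sd))`, reflecting
#'   non-uniform water supply between pots.
#' @param margin_mix_max Maximum leaf fraction mixed into soil pixels within
#'   4 px of the rosette margin (partial-volume overhang; default 0.35, 0
#'   disables).
#' @param shift Integer `c(dy, dx)` applied to the fluorescence cube
#'   (default `c(0, -10)`: 10 pixels left).
#' @param seed Integer seed; fully determines the rendered scene.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(lines = 96L, samples = 96L,
                         wavelengths = reduced_wavelengths(),
                         pot_rows = 1L, pot_cols = 1L, pot_size = 56L,
                         leaf_radius = 18L, panel_lines = 12L,
                         treatment = "control", drought_effect = 1.15,
                         leaf_deficit = 0, chlorophyll = 0.8,
                         chlorophyll_sd = 0.005, nir_structure_sd = 0.15,
                         soil_slope_sd = 0.12, mult_noise_sd = 0.03,
                         add_noise_sd = 0.4, pot_chl_sd = 0.02,
                         pot_nir_sd = 0.05, pot_gain_sd = 0.05,
                         pot_band_shift_sd = 0.15, pot_response_sd = 0.35,
                         margin_mix_max = 0.35, shift = c(0L, -10L),
                         seed = 1L) {
  n_pots <- pot_rows * pot_cols
  spec <- list(lines = as.integer(lines), samples = as.integer(samples),
               wavelengths = wavelengths,
               pot_rows = as.integer(pot_rows), pot_cols = as.integer(pot_cols),
               pot_size = as.integer(pot_size),
               leaf_radius = as.numeric(leaf_radius),
               panel_lines = as.integer(panel_lines),
               treatment = rep_len(treatment, n_pots),
               drought_effect = drought_effect, leaf_deficit = leaf_deficit,
               chlorophyll = chlorophyll, chlorophyll_sd = chlorophyll_sd,
               nir_structure_sd = nir_structure_sd,
               soil_slope_sd = soil_slope_sd,
               mult_noise_sd = mult_noise_sd, add_noise_sd = add_noise_sd,
               pot_chl_sd = pot_chl_sd, pot_nir_sd = pot_nir_sd,
               pot_gain_sd = pot_gain_sd,
               pot_band_shift_sd = pot_band_shift_sd,
               pot_response_sd = pot_response_sd,
               margin_mix_max = margin_mix_max,
               shift = as.integer(shift), seed = as.integer(seed))
  if (drought_effect < 1)
    stop("drought_effect must be >= 1 (drought elevates red-edge reflectance)")
  avail_lines <- lines - panel_lines
  if (pot_rows * pot_size > avail_lines || pot_cols * pot_size > samples)
    stop("layout error: pots do not fit beside the panel strip")
  structure(spec, class = "phantom_spec")
}

#' Tray preset mirroring the pilot drought study
#'
#' One 2x3 tray of six pots under a single treatment, scan lines spanning a
#' panel strip plus the tray.
#'
#' @param treatment `"control"` or `"drought"` for the whole tray.
#' @param seed Integer seed.
#' @param leaf_deficit Fractional leaf-area deficit of drought pots.
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
drought_tray_spec <- function(treatment = "control", seed = 1L,
                              leaf_deficit = 0, ...) {
  phantom_spec(lines = 80L, samples = 102L, pot_rows = 2L, pot_cols = 3L,
               pot_size = 32L, leaf_radius = 10.5, panel_lines = 12L,
               treatment = treatment, leaf_deficit = leaf_deficit,
               seed = seed, ...)
}

# Class codes of the ground-truth map.
.phantom_classes <- c(background = 0L, leaf = 1L, soil = 2L, pot = 3L,
                      panel = 4L)

# Build the per-pixel class map and per-pot leaf geometry.
render_class_map <- function(spec) {
  cm <- matrix(.phantom_classes[["background"]], spec$lines, spec$samples)
  cm[seq_len(spec$panel_lines), ] <- .phantom_classes[["panel"]]
  pot_of <- matrix(0L, spec$lines, spec$samples)
  avail_lines <- spec$lines - spec$panel_lines
  gap_y <- (avail_lines - spec$pot_rows * spec$pot_size) %/% (spec$pot_rows + 1L)
  gap_x <- (spec$samples - spec$pot_cols * spec$pot_size) %/% (spec$pot_cols + 1L)
  yy <- matrix(seq_len(spec$lines), spec$lines, spec$samples)
  xx <- matrix(seq_len(spec$samples), spec$lines, spec$samples, byrow = TRUE)
  pot_id <- 0L
  centers <- list()
  for (i in seq_len(spec$pot_rows)) {
    for (j in seq_len(spec$pot_cols)) {
      pot_id <- pot_id + 1L
      y0 <- spec$panel_lines + gap_y * i + spec$pot_size * (i - 1L) + 1L
      x0 <- gap_x * j + spec$pot_size * (j - 1L) + 1L
      ys <- y0:(y0 + spec$pot_size - 1L); xs <- x0:(x0 + spec$pot_size - 1L)
      cm[ys, xs] <- .phantom_classes[["pot"]]
      inner <- 2L
      cm[ys[-c(seq_len(inner), length(ys) + 1L - seq_len(inner))],
         xs[-c(seq_len(inner), length(xs) + 1L - seq_len(inner))]] <-
        .phantom_classes[["soil"]]
      cy <- y0 + (spec$pot_size - 1L) / 2; cx <- x0 + (spec$pot_size - 1L) / 2
      r <- spec$leaf_radius
      if (spec$treatment[pot_id] == "drought" && spec$leaf_deficit > 0)
        r <- r * sqrt(1 - spec$leaf_deficit)
      r <- r * stats::runif(1, 0.96, 1.04)   # pot-to-pot size variability
      # lobed rosette margin
      theta <- atan2(yy - cy, xx - cx)
      rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
      margin <- r * (1 + 0.08 * sin(5 * theta + pot_id))
      leaf <- rr <= margin & cm == .phantom_classes[["soil"]]
      cm[leaf] <- .phantom_classes[["leaf"]]
      pot_of[ys, xs] <- pot_id
      centers[[pot_id]] <- c(cy, cx)
    }
  }
  list(class_map = cm, pot_of = pot_of, centers = centers)
}

#' Render a phantom scene
#'
#' Composes paired reflectance and fluorescence hypercubes from parametric
#' endmember spectra over the scene's class map, with per-pixel chlorophyll
#' jitter, multiplicative lognormal noise, additive detector noise, the
#' drought red-edge plateau on leaves of drought pots, and the configured
#' integer shift applied to the fluorescence cube. The seed fully determines
#' the output.
#'
#' @param spec A `phantom_spec`.
#' @param raw Also return 300-band raw-intensity variants (12-bit counts
#'   under a synthetic illumination spectrum, 4x cross-track upsampled) for
#'   testing binning and flat-field correction.
#' @return List: `reflectance` and `fluorescence` [hypercube]s (reduced
#'   geometry; reflectance in percent), `truth` (a `phantom_truth`:
#'   class map, per-pot treatment and true leaf pixel counts, applied shift,
#'   endmembers), and when `raw = TRUE` also `raw_reflectance` and
#'   `panel_region`.
#' @export
render_scene <- function(spec, raw = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  geom <- render_class_map(spec)
  cm <- geom$class_map
  wl <- spec$wavelengths
  nb <- length(wl)
  npix <- length(cm)
  cls <- as.vector(cm)
  refl <- matrix(0, npix, nb)

  panel_px <- cls == .phantom_classes[["panel"]]
  soil_px <- cls == .phantom_classes[["soil"]]
  pot_px <- cls == .phantom_classes[["pot"]]
  bg_px <- cls == .phantom_classes[["background"]]
  leaf_px <- cls == .phantom_classes[["leaf"]]

  refl[panel_px, ] <- 1.0
  if (any(bg_px)) refl[bg_px, ] <- 0.06
  if (any(pot_px))
    refl[pot_px, ] <- matrix(rep(soil_spectrum(wl, 0.16, 0.06),
                                 each = sum(pot_px)), sum(pot_px), nb)
  if (any(soil_px)) {
    slopes <- stats::rnorm(sum(soil_px), 0.22, spec$soil_slope_sd)
    soil_spec <- 0.12 + outer(slopes, (wl - 408) / 593)
    # organic matter / iron oxide variability: variable blue absorption
    soil_spec <- soil_spec -
      outer(abs(stats::rnorm(sum(soil_px), 0, 0.03)), gauss(wl, 460, 40))
    # partial-volume contamination: soil near the rosette margin sees a
    # random fraction of overhanging leaf
    near_leaf <- leaf_px
    dim(near_leaf) <- dim(cm)
    for (i in 1:4) {
      near_leaf <- near_leaf |
        shift_matrix(near_leaf, 1, 0) | shift_matrix(near_leaf, -1, 0) |
        shift_matrix(near_leaf, 0, 1) | shift_matrix(near_leaf, 0, -1)
    }
    contam <- as.vector(near_leaf)[soil_px]
    beta <- ifelse(contam, stats::runif(sum(soil_px), 0, spec$margin_mix_max), 0)
    pure_leaf <- vegetation_spectrum(spec$chlorophyll, wl)
    soil_spec <- soil_spec * (1 - beta) + outer(beta, pure_leaf)
    refl[soil_px, ] <- soil_spec
  }
  if (any(leaf_px)) {
    n_leaf <- sum(leaf_px)
    n_pots <- length(geom$centers)
    pot_idx <- as.vector(geom$pot_of)[leaf_px]
    # pot-level random effects: plant-to-plant variability shared by all
    # leaf pixels of one pot
    pot_chl <- stats::rnorm(n_pots, 0, spec$pot_chl_sd)
    pot_nir <- stats::rnorm(n_pots, 0, spec$pot_nir_sd)
    pot_gain <- exp(stats::rnorm(n_pots, 0, spec$pot_gain_sd))
    pot_shift <- stats::rnorm(n_pots, 0, spec$pot_band_shift_sd)
    pot_logboost <- log(spec$drought_effect) *
      exp(stats::rnorm(n_pots, 0, spec$pot_response_sd))
    chl <- pmin(1, pmax(0.05,
      stats::rnorm(n_leaf, spec$chlorophyll, spec$chlorophyll_sd) +
        pot_chl[pot_idx]))
    shift_nm <- stats::rnorm(n_leaf, 0, 1.0) + # pigment band-position jitter
      pot_shift[pot_idx]
    green_nm <- stats::rnorm(n_leaf, 0, 2)    # green-peak position jitter
    leaf_spec <- t(vapply(seq_len(n_leaf), function(i)
      vegetation_spectrum(chl[i], wl, band_shift = shift_nm[i],
                          green_shift = green_nm[i]),
      numeric(nb)))
    # structural NIR variability (leaf stacking and angle): scales the red
    # edge and NIR plateau, leaving pigment-dominated visible bands alone
    wnir <- logistic((wl - 725) / 12)
    eta <- stats::rnorm(n_leaf, 0, spec$nir_structure_sd)
    # pot-level canopy density acts deeper in the NIR than per-pixel
    # leaf-angle variation
    wnir_pot <- logistic((wl - 745) / 12)
    leaf_spec <- leaf_spec *
      (1 + outer(eta, wnir) + outer(pot_nir[pot_idx], wnir_pot)) *
      pot_gain[pot_idx]
    stressed <- spec$treatment[pot_idx] == "drought"
    if (any(stressed) && spec$drought_effect > 1) {
      plateau <- wl >= 685 & wl <= 700
      leaf_spec[stressed, plateau] <-
        leaf_spec[stressed, plateau] * exp(pot_logboost[pot_idx[stressed]])
    }
    refl[leaf_px, ] <- pmax(leaf_spec, 0.005)
  }
  # no scene material is truly black; floor keeps ratio denominators sane
  refl <- pmax(refl, 0.02)
  # imaging noise: per-pixel multiplicative lognormal + per-value additive
  mult <- exp(stats::rnorm(npix, 0, spec$mult_noise_sd))
  refl_pct <- refl * 100 * mult +
    matrix(stats::rnorm(npix * nb, 0, spec$add_noise_sd), npix, nb)
  refl_pct[refl_pct < 0] <- 0
  refl_cube <- hypercube(array(refl_pct, dim = c(spec$lines, spec$samples, nb)),
                         wl, modality = "reflectance",
                         resolution = c(1, 1))

  # fluorescence: emission on leaf pixels, scaled by chlorophyll, then shifted
  fl <- matrix(0, npix, nb)
  emission <- fluorescence_spectrum(wl)
  if (any(leaf_px)) {
    amp <- 800 * pmin(1, pmax(0.05, stats::rnorm(sum(leaf_px),
                                                 spec$chlorophyll,
                                                 spec$chlorophyll_sd)))
    fl[leaf_px, ] <- outer(amp * exp(stats::rnorm(sum(leaf_px), 0,
                                                  spec$mult_noise_sd)),
                           emission)
  }
  fl <- fl + matrix(abs(stats::rnorm(npix * nb, 0, 2)), npix, nb)
  fl_cube <- hypercube(array(fl, dim = c(spec$lines, spec$samples, nb)),
                       wl, modality = "fluorescence", resolution = c(1, 1))
  fl_cube <- apply_shift(fl_cube, spec$shift)

  leaf_counts <- vapply(seq_along(geom$centers), function(p)
    sum(cm == .phantom_classes[["leaf"]] & geom$pot_of == p), integer(1))
  truth <- structure(
    list(class_map = cm, classes = .phantom_classes, pot_of = geom$pot_of,
         treatment = spec$treatment, leaf_counts = leaf_counts,
         shift = spec$shift,
         endmembers = list(
           leaf = vegetation_spectrum(spec$chlorophyll, wl),
           soil = soil_spectrum(wl), fluorescence = emission)),
    class = "phantom_truth")
  out <- list(reflectance = refl_cube, fluorescence = fl_cube, truth = truth)

  if (raw) {
    cal <- calibration_preset()
    wl_raw <- calibration_wavelengths(cal)
    # smooth LED-composite illumination spectrum (counts at 100% reflectance)
    illum <- 1200 + 1800 * gauss(wl_raw, 650, 180) + 900 * gauss(wl_raw, 850, 90)
    # the reduced pixel is the physical measurement; raw samples are
    # synthetic sub-samples of it, so binning + flat-fielding recovers the
    # rendered reflectance cube (noise included) up to count noise
    sidx <- rep(seq_len(spec$samples), each = 4L)
    bidx <- rep(seq_len(nb), each = 3L)
    arr <- refl_cube$data / 100
    arr <- arr[, sidx, bidx, drop = FALSE]
    counts <- sweep(arr, 3L, illum, "*")
    counts <- counts + array(stats::rnorm(length(counts), 0, 6), dim = dim(counts))
    counts <- round(pmin(pmax(counts, 0), 4095))
    out$raw_reflectance <- hypercube(counts, wl_raw, modality = "raw",
                                     resolution = c(1, 0.25))
    out$panel_region <- list(y = c(1L, spec$panel_lines),
                             x = c(1L, spec$samples * 4L))
  }
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d map, %d pots (%s)\n",
              nrow(x$class_map), ncol(x$class_map), length(x$leaf_counts),
              paste(x$treatment, collapse = ", ")))
  cat("  leaf pixels per pot:", paste(x$leaf_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth leaf mask of a phantom
#'
#' @param truth A `phantom_truth`.
#' @return Logical matrix: TRUE on leaf pixels.
#' @export
truth_leaf_mask <- function(truth) {
  truth$class_map == truth$classes[["leaf"]]
}

#' Sample labeled ROI spectra from a phantom using its ground truth
#'
#' Draws pixels of the requested classes from the class map and extracts
#' their spectra, labeled with the field convention (first class = 1, second
#' = 2). Stands in for the manual ROI selection done on real scenes.
#'
#' @param cube A [hypercube] of the same scene.
#' @param truth The scene's `phantom_truth`.
#' @param classes Character vector of two class names (default leaf, soil).
#' @param n Pixels sampled per class.
#' @param seed Integer seed.
#' @return A `labeled_spectra`.
#' @export
truth_roi_spectra <- function(cube, truth, classes = c("leaf", "soil"),
                              n = 400L, seed = 1L) {
  set.seed(seed)
  spectra <- NULL; labels <- integer(0)
  flat <- as_spectra_matrix(cube)
  for (i in seq_along(classes)) {
    idx <- which(as.vector(truth$class_map) == truth$classes[[classes[i]]])
    if (length(idx) == 0L) stop("no pixels of class ", classes[i])
    take <- sample(idx, min(n, length(idx)))
    spectra <- rbind(spectra, flat[take, , drop = FALSE])
    labels <- c(labels, rep(i, length(take)))
  }
  labeled_spectra(spectra, labels, cube$wavelengths)
}
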