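# Non-overlapping block means along one array dimension. Elements beyond the
# last complete block are dropped (floor division).
block_mean_along <- function(arr, dim_idx, factor) {
  d <- dim(arr)
  n_out <- d[dim_idx] %/% factor
  if (n_out < 1L)
    stop("factor ", factor, " exceeds dimension of size ", d[dim_idx])
  perm <- c(dim_idx, setdiff(seq_along(d), dim_idx))
  ap <- aperm(arr, perm)
  dim(ap) <- c(d[dim_idx], prod(d[-dim_idx]))
  ap <- ap[seq_len(n_out * factor), , drop = FALSE]
  m <- matrix(ap, nrow = factor)
  means <- colMeans(m)
  out <- array(means, dim = c(n_out, d[-dim_idx]))
  aperm(out, order(perm))
}

#' Spectral and cross-track block averaging
#'
#' Smooths a raw hypercube by averaging non-overlapping groups of neighboring
#' pixels: `spectral_factor` along the band axis and `cross_track_factor`
#' along the cross-track (sample) axis. No averaging is applied along the
#' scan direction. With the defaults (3, 4), a 1200-sample, 300-band raw cube
#' reduces to 300 samples and 100 bands, and a 1.98 nm spectral interval
#' becomes 5.94 nm. Trailing pixels that do not fill a complete block are
#' dropped. Output wavelengths are the means of each averaged wavelength
#' group.
#'
#' @param cube A [hypercube].
#' @param spectral_factor Block size along the band axis (default 3).
#' @param cross_track_factor Block size along the sample axis (default 4).
#' @return The binned [hypercube].
#' @export
bin_cube <- function(cube, spectral_factor = 3L, cross_track_factor = 4L) {
  if (spectral_factor < 1L || cross_track_factor < 1L)
    stop("binning factors must be >= 1")
  d <- dim(cube$data)
  if (spectral_factor > d[3L])
    stop("spectral_factor exceeds band count")
  if (cross_track_factor > d[2L])
    stop("cross_track_factor exceeds sample count")
  data <- cube$data
  if (cross_track_factor > 1L) data <- block_mean_along(data, 2L, cross_track_factor)
  if (spectral_factor > 1L) data <- block_mean_along(data, 3L, spectral_factor)
  nb <- d[3L] %/% spectral_factor
  wl_groups <- matrix(cube$wavelengths[seq_len(nb * spectral_factor)],
                      nrow = spectral_factor)
  out <- cube
  out$data <- data
  out$wavelengths <- colMeans(wl_groups)
  if (!is.na(out$resolution[2L]))
    out$resolution[2L] <- out$resolution[2L] * cross_track_factor
  out
}

#' Extract the reference-panel spectrum
#'
#' Averages all pixels of the mounted reflectance-standard panel region,
#' band by band, to obtain the flat-field reference spectrum.
#'
#' @param cube A [hypercube] (raw or binned intensities).
#' @param panel_region List with `y = c(first, last)` and `x = c(first, last)`
#'   (1-based inclusive) delimiting the panel strip.
#' @param nominal_percent Nominal panel reflectance (default 100).
#' @param floor Intensity floor; a warning is raised if any band's panel mean
#'   falls below it (dark or saturated panel check).
#' @return A `panel_reference` object with the per-band mean spectrum.
#' @export
extract_panel_reference <- function(cube, panel_region,
                                    nominal_percent = 100, floor = 0) {
  sub <- crop_cube(cube, y = panel_region$y, x = panel_region$x)
  spectrum <- colMeans(as_spectra_matrix(sub))
  if (any(spectrum <= 0))
    stop("unusable panel reference: non-positive mean intensity in some band")
  if (any(spectrum < floor))
    warning("panel mean below floor (", floor, ") in ",
            sum(spectrum < floor), " band(s)")
  structure(
    list(spectrum = unname(spectrum), wavelengths = cube$wavelengths,
         panel_region = panel_region, nominal_percent = nominal_percent),
    class = "panel_reference")
}

#' Flat-field correction to percent reflectance
#'
#' Converts intensity to relative reflectance by ratio to the reference-panel
#' spectrum: `reflectance = (I - dark) / (ref - dark) * nominal`. The
#' default dark spectrum is zero (pure panel ratio). Values above 100% are
#' permitted (specular pixels) and counted in the `n_specular` attribute.
#'
#' @param cube A [hypercube] of intensities.
#' @param ref A `panel_reference` with the same band count as `cube`.
#' @param dark Optional per-band dark-current spectrum (default 0).
#' @return A reflectance [hypercube] (percent).
#' @export
flat_field_correct <- function(cube, ref, dark = NULL) {
  nb <- dim(cube$data)[3L]
  if (length(ref$spectrum) != nb)
    stop("band count mismatch: cube has ", nb, " bands, reference ",
         length(ref$spectrum))
  if (is.null(dark)) dark <- rep(0, nb)
  if (length(dark) == 1L) dark <- rep(dark, nb)
  if (length(dark) != nb) stop("dark spectrum length must match band count")
  denom <- ref$spectrum - dark
  if (any(denom <= 0)) stop("reference minus dark must be positive in every band")
  d <- dim(cube$data)
  scale <- ref$nominal_percent / denom
  out <- cube
  out$data <- (cube$data - rep(dark, each = d[1L] * d[2L])) *
    rep(scale, each = d[1L] * d[2L])
  out$data[out$data < 0] <- 0
  out$modality <- "reflectance"
  attr(out, "n_specular") <- sum(out$data > ref$nominal_percent)
  out
}
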