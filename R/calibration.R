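#' Fit the spectral calibration of the camera
#'
#' Maps detector pixel indices along the spectral axis to wavelengths with an
#' ordinary least-squares affine model, the standard procedure with pencil
#' calibration lamps whose emission lines have known wavelengths.
#'
#' @param pixels Integer detector pixel indices of identified lamp lines, or
#'   a two-column matrix/data.frame of (pixel, wavelength) pairs.
#' @param wavelengths Known line wavelengths in nm (omit if `pixels` is
#'   two-column).
#' @return A `spectral_calibration` object with fields `slope` (nm/pixel),
#'   `intercept` (nm), `pixel_min`, `pixel_max`, `n_bands`.
#' @examples
#' cal <- fit_spectral_calibration(c(401, 700), c(408, 1001))
#' cal$slope  # ~1.98 nm per pixel
#' @export
fit_spectral_calibration <- function(pixels, wavelengths = NULL) {
  if (is.null(wavelengths)) {
    m <- as.matrix(pixels)
    if (ncol(m) != 2L) stop("expected two columns: pixel, wavelength")
    pixels <- m[, 1L]; wavelengths <- m[, 2L]
  }
  pixels <- as.numeric(pixels); wavelengths <- as.numeric(wavelengths)
  if (length(pixels) != length(wavelengths))
    stop("'pixels' and 'wavelengths' must have equal length")
  if (length(unique(pixels)) < 2L)
    stop("degenerate fit: need at least 2 distinct pixel indices")
  fit <- stats::lm(wavelengths ~ pixels)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0) stop("fitted slope must be positive (wavelength increasing in pixel)")
  pmin <- as.integer(min(pixels)); pmax <- as.integer(max(pixels))
  structure(
    list(slope = slope, intercept = intercept,
         pixel_min = pmin, pixel_max = pmax,
         n_bands = pmax - pmin + 1L),
    class = "spectral_calibration")
}

#' @export
print.spectral_calibration <- function(x, ...) {
  cat(sprintf("<spectral_calibration> wavelength = %.4f * pixel + %.3f nm\n",
              x$slope, x$intercept))
  cat(sprintf("  valid pixels %d-%d (%d bands), span %.1f-%.1f nm\n",
              x$pixel_min, x$pixel_max, x$n_bands,
              pixel_to_wavelength(x, x$pixel_min),
              pixel_to_wavelength(x, x$pixel_max)))
  invisible(x)
}

#' Default VNIR calibration preset
#'
#' The shipped preset maps detector pixels 401–700 to 408–1001 nm (300
#' collected spectral pixels at a 1.98 nm interval), fitted from the endpoint
#' correspondence.
#'
#' @return A `spectral_calibration`.
#' @export
calibration_preset <- function() {
  fit_spectral_calibration(c(401, 700), c(408, 1001))
}

#' Convert detector pixel index to wavelength
#'
#' @param cal A `spectral_calibration`.
#' @param pixel Integer pixel index (vectorized), within the valid range.
#' @return Wavelength(s) in nm.
#' @export
pixel_to_wavelength <- function(cal, pixel) {
  if (any(pixel < cal$pixel_min | pixel > cal$pixel_max))
    stop(sprintf("pixel outside valid range [%d, %d]",
                 cal$pixel_min, cal$pixel_max))
  cal$slope * pixel + cal$intercept
}

#' Wavelength grid of all collected spectral pixels
#'
#' @param cal A `spectral_calibration`.
#' @return Numeric vector of length `cal$n_bands`.
#' @export
calibration_wavelengths <- function(cal) {
  pixel_to_wavelength(cal, seq(cal$pixel_min, cal$pixel_max))
}

#' Plan a line-scan acquisition
#'
#' The stage moving speed is tied to the camera exposure time by the
#' reciprocal relationship V = 1/T (in mm/s and s): long exposures force slow
#' travel so that consecutive frames tile the scene without gaps. Duration
#' and along-track resolution follow from the line count and travel distance.
#'
#' @param exposure_T Camera exposure time in seconds.
#' @param distance Travel distance in mm.
#' @param n_lines Number of scan lines.
#' @param speed Optional speed override in mm/s for platforms where the
#'   reciprocal relationship does not hold; default `1 / exposure_T`.
#' @return A `scan_plan` object.
#' @examples
#' plan_scan(0.05, distance = 800, n_lines = 800)  # 20 mm/s, 40 s, 1 mm/pixel
#' @export
plan_scan <- function(exposure_T, distance, n_lines, speed = NULL) {
  if (exposure_T <= 0 || distance <= 0 || n_lines < 1)
    stop("exposure_T, distance must be positive and n_lines >= 1")
  if (is.null(speed)) speed <- 1 / exposure_T
  if (speed <= 0) stop("speed must be positive")
  structure(
    list(exposure_T = exposure_T, speed_V = speed,
         n_lines = as.integer(n_lines), distance = distance,
         duration = n_lines * exposure_T,
         along_track_resolution = distance / n_lines),
    class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat("<scan_plan>\n")
  cat(sprintf("  exposure: %g s   speed: %g mm/s\n", x$exposure_T, x$speed_V))
  cat(sprintf("  %d lines over %g mm -> %g s, %g mm/pixel along track\n",
              x$n_lines, x$distance, x$duration, x$along_track_resolution))
  invisible(x)
}

#' Cross-track spatial resolution
#'
#' Resolution along the scan line is the instantaneous-field-of-view length
#' divided by the number of spatial detector pixels.
#'
#' @param ifov_length IFOV length on the sample plane in mm.
#' @param n_samples Number of cross-track spatial pixels.
#' @return mm per pixel.
#' @examples
#' cross_track_resolution(484, 1936)  # 0.25 mm/pixel
#' @export
cross_track_resolution <- function(ifov_length, n_samples) {
  if (ifov_length <= 0 || n_samples <= 0)
    stop("ifov_length and n_samples must be positive")
  ifov_length / n_samples
}
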