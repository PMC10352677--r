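#' Construct a hypercube
#'
#' A hypercube is the pipeline's universal currency: a 3-D numeric array
#' indexed (line Y, sample X, band \eqn{\lambda}) together with the band-center
#' wavelengths, a modality tag, and the spatial resolution of the two spatial
#' axes. Line-scan (pushbroom) systems build the Y axis one scan line at a
#' time; X is the cross-track axis along the sensor's slit.
#'
#' @param data 3-D numeric array with dimensions (lines, samples, bands).
#' @param wavelengths Numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length equal to `dim(data)[3]`.
#' @param modality One of `"raw"` (detector counts), `"reflectance"`
#'   (percent, panel-referenced) or `"fluorescence"` (counts under UV-A
#'   excitation).
#' @param timestamp Optional acquisition time string.
#' @param resolution Numeric length-2 vector, mm/pixel along (Y, X).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths,
                      modality = c("raw", "reflectance", "fluorescence"),
                      timestamp = NULL, resolution = c(NA_real_, NA_real_)) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array (lines, samples, bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length of 'wavelengths' (", length(wavelengths),
         ") must equal the band dimension (", dim(data)[3L], ")")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing")
  if (modality == "reflectance" && any(data < 0, na.rm = TRUE))
    stop("reflectance values must be non-negative")
  structure(
    list(data = data, wavelengths = wavelengths, modality = modality,
         timestamp = timestamp, resolution = as.numeric(resolution)),
    class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands [%s]\n",
              d[1L], d[2L], d[3L], x$modality))
  cat(sprintf("  wavelengths: %.2f-%.2f nm (interval ~%.2f nm)\n",
              min(x$wavelengths), max(x$wavelengths),
              if (length(x$wavelengths) > 1L) mean(diff(x$wavelengths)) else NA))
  if (!all(is.na(x$resolution)))
    cat(sprintf("  resolution: %.3g x %.3g mm/pixel (Y x X)\n",
                x$resolution[1L], x$resolution[2L]))
  if (!is.null(x$timestamp)) cat("  acquired:", x$timestamp, "\n")
  invisible(x)
}

#' Index of the band nearest a target wavelength
#'
#' @param wavelengths Numeric vector of band centers in nm (or a `hypercube`).
#' @param nm Target wavelength in nm; must lie within the spanned range.
#' @return Integer band index.
#' @export
nearest_band <- function(wavelengths, nm) {
  if (inherits(wavelengths, "hypercube")) wavelengths <- wavelengths$wavelengths
  if (nm < min(wavelengths) || nm > max(wavelengths))
    stop(sprintf("wavelength %.1f nm outside cube span [%.1f, %.1f]",
                 nm, min(wavelengths), max(wavelengths)))
  which.min(abs(wavelengths - nm))
}

#' Extract a single-band image
#'
#' @param cube A `hypercube`.
#' @param nm Wavelength in nm (mapped to the nearest band center).
#' @return Matrix (lines x samples).
#' @export
band_image <- function(cube, nm) {
  b <- nearest_band(cube$wavelengths, nm)
  cube$data[, , b]
}

#' Crop a hypercube spatially
#'
#' Ranges are 1-based and inclusive, the native R convention. The spectral
#' axis is never altered by cropping.
#'
#' @param cube A `hypercube`.
#' @param y,x Integer length-2 vectors `c(first, last)`; `NULL` keeps the
#'   full extent of that axis.
#' @return The cropped `hypercube`.
#' @export
crop_cube <- function(cube, y = NULL, x = NULL) {
  d <- dim(cube$data)
  if (is.null(y)) y <- c(1L, d[1L])
  if (is.null(x)) x <- c(1L, d[2L])
  check_range <- function(r, n, axis) {
    if (length(r) != 2L || r[1L] > r[2L])
      stop("empty ", axis, " range")
    if (r[1L] < 1L || r[2L] > n)
      stop(axis, " range [", r[1L], ", ", r[2L], "] out of bounds (1..", n, ")")
  }
  check_range(y, d[1L], "y"); check_range(x, d[2L], "x")
  out <- cube
  out$data <- cube$data[y[1L]:y[2L], x[1L]:x[2L], , drop = FALSE]
  out
}

#' Flatten masked pixels to a spectra matrix
#'
#' @param cube A `hypercube`.
#' @param mask Logical matrix with the cube's spatial shape, or `NULL` for
#'   all pixels.
#' @return Numeric matrix, one row per pixel, one column per band.
#' @export
as_spectra_matrix <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  m <- matrix(cube$data, nrow = d[1L] * d[2L], ncol = d[3L])
  if (!is.null(mask)) {
    mask <- as_mask_matrix(mask)
    if (!all(dim(mask) == d[1:2]))
      stop("mask shape does not match cube spatial shape")
    m <- m[as.vector(mask), , drop = FALSE]
  }
  colnames(m) <- sprintf("%.2f", cube$wavelengths)
  m
}

# Accept plant_mask objects or plain logical matrices.
as_mask_matrix <- function(mask) {
  if (inherits(mask, "plant_mask")) mask <- mask$mask
  if (is.matrix(mask)) return(mask != 0)
  stop("'mask' must be a matrix or plant_mask")
}
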