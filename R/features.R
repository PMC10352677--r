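#' Summarize masked spectra
#'
#' Per-band mean and standard deviation over all mask pixels.
#'
#' @param cube A [hypercube].
#' @param mask A `plant_mask` or logical matrix (non-empty).
#' @return A `spectra_summary`: data frame `table` (wavelength, mean, sd)
#'   plus `n` pixels.
#' @export
summarize_spectra <- function(cube, mask) {
  m <- as_spectra_matrix(cube, mask)
  if (nrow(m) == 0L) stop("empty mask")
  mu <- colMeans(m)
  sdv <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) else rep(0, ncol(m))
  structure(
    list(table = data.frame(wavelength = cube$wavelengths,
                            mean = unname(mu), sd = unname(sdv)),
         n = nrow(m), modality = cube$modality),
    class = "spectra_summary")
}

#' @export
print.spectra_summary <- function(x, ...) {
  cat(sprintf("<spectra_summary> %d pixels, %d bands [%s]\n",
              x$n, nrow(x$table), x$modality))
  invisible(x)
}

#' Leaf-area series from mask images
#'
#' Estimates total leaf area by counting plant pixels in each mask, the
#' standard daily growth readout.
#'
#' @param masks List of `plant_mask` objects or logical matrices.
#' @param day,tray,treatment Optional vectors (recycled) annotating each
#'   mask.
#' @return Data frame (day, tray, treatment, pixels).
#' @export
leaf_area <- function(masks, day = seq_along(masks), tray = 1L,
                      treatment = NA_character_) {
  pixels <- vapply(masks, function(m) sum(as_mask_matrix(m)), integer(1))
  data.frame(day = rep_len(day, length(masks)),
             tray = rep_len(tray, length(masks)),
             treatment = rep_len(treatment, length(masks)),
             pixels = pixels)
}

#' Compare control and drought leaf areas
#'
#' Welch two-sample t-test (pooled-variance optionally) on pixel counts,
#' with the percent leaf-area deficit of the drought group relative to
#' control.
#'
#' @param control,drought Numeric vectors of leaf pixel counts (>= 2 each).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List: `t`, `p_value`, `percent_difference`
#'   (`(mean_c - mean_d) / mean_c * 100`), `mean_control`, `mean_drought`.
#' @export
leaf_area_test <- function(control, drought, var_equal = FALSE) {
  if (length(control) < 2L || length(drought) < 2L)
    stop("need at least 2 samples per group")
  if (stats::sd(control) == 0 && stats::sd(drought) == 0) {
    # degenerate case t.test() refuses: constant groups
    d <- mean(control) - mean(drought)
    tt <- list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
               p.value = as.numeric(d == 0))
  } else {
    tt <- stats::t.test(control, drought, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       percent_difference = (mean(control) - mean(drought)) / mean(control) * 100,
       mean_control = mean(control), mean_drought = mean(drought))
}

#' Normalize spectra at a reference band
#'
#' Divides each spectrum by its value at the band nearest `lambda_ref`
#' (e.g. 702 nm for red-edge comparisons), removing overall brightness
#' differences.
#'
#' @param spectra Matrix (row per spectrum) or numeric vector.
#' @param wavelengths Band centers in nm.
#' @param lambda_ref Reference wavelength in nm.
#' @return Normalized spectra, same shape as input; value 1 at the
#'   reference band.
#' @export
normalize_at_band <- function(spectra, wavelengths, lambda_ref) {
  vec <- is.null(dim(spectra))
  m <- if (vec) matrix(spectra, nrow = 1L) else as.matrix(spectra)
  b <- nearest_band(wavelengths, lambda_ref)
  ref <- m[, b]
  if (any(ref == 0)) stop("zero value at reference band")
  out <- m / ref
  if (vec) as.vector(out) else out
}

#' Average-window outlier filter
#'
#' Reduces masked plant pixels to window-mean spectra while discarding
#' high-variation areas (e.g. leaf margins). The masked bounding box is tiled
#' with non-overlapping `window` x `window` blocks from its top-left corner;
#' only fully-masked blocks participate. Global statistics M and SD of the
#' driver band image (default the high-reflectance R815 band) are computed
#' over all masked pixels; a block is removed when more than
#' `frac_threshold` of its pixels (i.e. >= 1 of 9 at the defaults) fall
#' outside `M +/- k_sd * SD`. Each surviving block contributes the spatial
#' mean of its pixel spectra.
#'
#' @param cube A [hypercube] (reflectance).
#' @param mask A `plant_mask` or logical matrix.
#' @param band_nm Driver wavelength for the outlier rule (default 815 nm).
#' @param window Block edge length (default 3).
#' @param frac_threshold Removal threshold as a fraction of window pixels
#'   (default 0.10).
#' @param k_sd Outlier fence width in global SDs (default 3).
#' @return A `window_filter_result`: `spectra` (matrix, one row per retained
#'   window), `window_info` (data frame of grid positions and status:
#'   kept/removed/partial), `M`, `SD`, `counts` (pixel accounting),
#'   `wavelengths`.
#' @export
window_filter <- function(cube, mask, band_nm = 815, window = 3L,
                          frac_threshold = 0.10, k_sd = 3) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("empty mask")
  band <- band_image(cube, band_nm)
  vals <- band[m]
  M <- mean(vals); SD <- stats::sd(vals)
  if (is.na(SD)) SD <- 0
  lo <- M - k_sd * SD; hi <- M + k_sd * SD
  ys <- range(which(rowSums(m) > 0)); xs <- range(which(colSums(m) > 0))
  ny <- (ys[2L] - ys[1L] + 1L) %/% window
  nx <- (xs[2L] - xs[1L] + 1L) %/% window
  info <- list(); spectra <- list()
  n_kept <- 0L; n_removed <- 0L; n_partial <- 0L
  masked_partial <- 0L; masked_in_kept <- 0L; masked_in_removed <- 0L
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1L] * d[2L], ncol = d[3L])
  for (gy in seq_len(ny)) {
    for (gx in seq_len(nx)) {
      y0 <- ys[1L] + (gy - 1L) * window
      x0 <- xs[1L] + (gx - 1L) * window
      yy <- y0:(y0 + window - 1L); xx <- x0:(x0 + window - 1L)
      sub <- m[yy, xx]
      n_masked <- sum(sub)
      if (n_masked == 0L) next
      if (n_masked < window^2) {
        n_partial <- n_partial + 1L
        masked_partial <- masked_partial + n_masked
        info[[length(info) + 1L]] <-
          data.frame(gy = gy, gx = gx, y0 = y0, x0 = x0, status = "partial")
        next
      }
      px <- band[yy, xx]
      n_out <- sum(px < lo | px > hi)
      if (n_out > frac_threshold * window^2) {
        n_removed <- n_removed + 1L
        masked_in_removed <- masked_in_removed + n_masked
        status <- "removed"
      } else {
        n_kept <- n_kept + 1L
        masked_in_kept <- masked_in_kept + n_masked
        lin <- as.vector(outer(yy, (xx - 1L) * d[1L], "+"))
        spectra[[length(spectra) + 1L]] <- colMeans(flat[lin, , drop = FALSE])
        status <- "kept"
      }
      info[[length(info) + 1L]] <-
        data.frame(gy = gy, gx = gx, y0 = y0, x0 = x0, status = status)
    }
  }
  spectra_mat <- if (length(spectra)) do.call(rbind, spectra) else
    matrix(numeric(0), 0L, d[3L])
  colnames(spectra_mat) <- sprintf("%.2f", cube$wavelengths)
  total_masked <- sum(m)
  counts <- list(
    n_kept = n_kept, n_removed = n_removed, n_partial = n_partial,
    masked_pixels_total = total_masked,
    masked_pixels_kept = masked_in_kept,
    masked_pixels_removed = masked_in_removed,
    masked_pixels_partial = masked_partial,
    masked_pixels_outside_tiling =
      total_masked - masked_in_kept - masked_in_removed - masked_partial)
  structure(
    list(spectra = spectra_mat,
         window_info = if (length(info)) do.call(rbind, info) else
           data.frame(gy = integer(0), gx = integer(0), y0 = integer(0),
                      x0 = integer(0), status = character(0)),
         M = M, SD = SD, window = as.integer(window),
         frac_threshold = frac_threshold, k_sd = k_sd,
         counts = counts, wavelengths = cube$wavelengths),
    class = "window_filter_result")
}

#' @export
print.window_filter_result <- function(x, ...) {
  cat(sprintf(
    "<window_filter_result> %dx%d windows: %d kept, %d removed, %d partial\n",
    x$window, x$window, x$counts$n_kept, x$counts$n_removed,
    x$counts$n_partial))
  cat(sprintf("  driver stats M = %.3f, SD = %.3f (fence %.3g SD)\n",
              x$M, x$SD, x$k_sd))
  invisible(x)
}

#' Pseudo-RGB rendering of a reflectance cube
#'
#' Builds a natural-color image from three configurable bands of the
#' reflectance hypercube, each channel stretched linearly between the given
#' percentiles of its own values.
#'
#' @param cube A [hypercube] spanning the visible range.
#' @param rgb_nm Wavelengths for the R, G, B channels (default 640, 550,
#'   460 nm).
#' @param stretch Lower/upper percentile for the contrast stretch.
#' @return Array (lines x samples x 3) in [0, 1].
#' @export
pseudo_rgb <- function(cube, rgb_nm = c(640, 550, 460),
                       stretch = c(0.01, 0.99)) {
  chans <- lapply(rgb_nm, function(nm) band_image(cube, nm))
  out <- array(0, dim = c(dim(chans[[1L]]), 3L))
  for (k in 1:3) {
    ch <- chans[[k]]
    q <- stats::quantile(ch, stretch, names = FALSE)
    rngw <- q[2L] - q[1L]
    sc <- if (rngw > 0) (ch - q[1L]) / rngw else ch * 0
    out[, , k] <- pmin(1, pmax(0, sc))
  }
  out
}
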