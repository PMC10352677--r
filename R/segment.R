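#' Extract labeled ROI spectra
#'
#' Pulls per-pixel spectra from labeled rectangular regions of interest.
#' The field convention labels lettuce 1 and soil 2; control/drought ROIs are
#' coded analogously. Ranges are 1-based inclusive.
#'
#' @param cube A [hypercube].
#' @param roi_defs Data frame with columns `label`, `y0`, `y1`, `x0`, `x1`.
#' @param average Average each ROI to a single spectrum instead of keeping
#'   per-pixel spectra (default `FALSE`).
#' @return A `labeled_spectra` object: `spectra` (matrix, row per spectrum),
#'   `labels` (integer vector), `wavelengths`.
#' @export
select_roi_spectra <- function(cube, roi_defs, average = FALSE) {
  req <- c("label", "y0", "y1", "x0", "x1")
  if (!all(req %in% names(roi_defs)))
    stop("roi_defs must have columns: ", paste(req, collapse = ", "))
  spectra <- NULL; labels <- integer(0)
  for (i in seq_len(nrow(roi_defs))) {
    r <- roi_defs[i, ]
    sub <- crop_cube(cube, y = c(r$y0, r$y1), x = c(r$x0, r$x1))
    m <- as_spectra_matrix(sub)
    if (average) m <- matrix(colMeans(m), nrow = 1L)
    spectra <- rbind(spectra, m)
    labels <- c(labels, rep(as.integer(r$label), nrow(m)))
  }
  labeled_spectra(spectra, labels, cube$wavelengths)
}

#' Construct a labeled spectra set
#'
#' @param spectra Matrix, one row per spectrum, one column per band.
#' @param labels Integer class codes, one per row.
#' @param wavelengths Band centers in nm.
#' @return A `labeled_spectra` object.
#' @export
labeled_spectra <- function(spectra, labels, wavelengths) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(labels))
    stop("one label per spectrum required")
  if (ncol(spectra) != length(wavelengths))
    stop("spectra column count must match wavelength count")
  structure(list(spectra = spectra, labels = as.integer(labels),
                 wavelengths = as.numeric(wavelengths)),
            class = "labeled_spectra")
}

#' Read / write ROI definitions
#'
#' Plain CSV with columns `label, y0, y1, x0, x1` (1-based inclusive ranges).
#'
#' @param path File path.
#' @return `read_roi` returns the ROI data frame.
#' @export
read_roi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "y0", "y1", "x0", "x1")
  if (!all(req %in% names(df)))
    stop("ROI file must have columns: ", paste(req, collapse = ", "))
  df[req]
}

#' @rdname read_roi
#' @param roi_defs ROI data frame to write.
#' @export
write_roi <- function(roi_defs, path) {
  utils::write.csv(roi_defs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Default ratio-denominator guard: small relative to the data scale.
default_epsilon <- function(values) {
  1e-6 * as.numeric(stats::quantile(values, 0.99, na.rm = TRUE))
}

#' Search all two-band reflectance ratios against class labels
#'
#' For every ordered band pair (l1 != l2), computes the Pearson correlation
#' between the per-spectrum ratio R(l1)/(R(l2)+epsilon) and the numeric class
#' labels, and selects the pair with the largest absolute correlation. This
#' is the screening step behind both leaf/soil background removal and the
#' red-edge drought-stress ratio.
#'
#' @param ls A `labeled_spectra` with at least two classes.
#' @param epsilon Positive guard added to denominators; default
#'   `1e-6 * (99th percentile of the spectra)`.
#' @return A `band_ratio_search` object: `correlation_surface` (bands x bands
#'   matrix, rows = numerator band l1, `NA` diagonal), `best_pair`
#'   (wavelengths), `best_idx`, `best_r`.
#' @export
band_ratio_search <- function(ls, epsilon = NULL) {
  if (length(unique(ls$labels)) < 2L)
    stop("need at least 2 distinct labels for a correlation search")
  if (is.null(epsilon)) epsilon <- default_epsilon(ls$spectra)
  if (epsilon <= 0) stop("epsilon must be positive")
  R <- ls$spectra
  y <- as.numeric(ls$labels)
  n <- nrow(R); nb <- ncol(R)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  surface <- matrix(NA_real_, nb, nb)
  for (j in seq_len(nb)) {
    M <- R / (R[, j] + epsilon)          # ratios with denominator band j
    Mc <- sweep(M, 2L, colMeans(M))
    sx <- sqrt(colSums(Mc^2))
    r <- as.vector(crossprod(Mc, yc)) / (sx * sy)
    r[!is.finite(r)] <- 0                # zero-variance ratio vectors
    surface[, j] <- r
  }
  diag(surface) <- NA_real_
  absr <- abs(surface)
  absr[is.na(absr)] <- -Inf
  best <- max(absr)
  # ties broken by smallest (l1, l2) in lexicographic wavelength order
  cand <- which(absr >= best - 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  bi <- cand[1L, ]
  dimnames(surface) <- list(sprintf("%.2f", ls$wavelengths),
                            sprintf("%.2f", ls$wavelengths))
  structure(
    list(correlation_surface = surface,
         best_pair = c(lambda1 = ls$wavelengths[bi[1L]],
                       lambda2 = ls$wavelengths[bi[2L]]),
         best_idx = c(bi[[1L]], bi[[2L]]),
         best_r = surface[bi[1L], bi[2L]],
         epsilon = epsilon, wavelengths = ls$wavelengths),
    class = "band_ratio_search")
}

#' @export
print.band_ratio_search <- function(x, ...) {
  cat(sprintf("<band_ratio_search> best ratio R%.0f/R%.0f, r = %.3f\n",
              x$best_pair[1L], x$best_pair[2L], x$best_r))
  invisible(x)
}

#' Two-band ratio image
#'
#' Pixelwise quotient of the single-band images nearest the two requested
#' wavelengths, enhancing contrast between materials with opposite spectral
#' trends (e.g. leaf vs soil).
#'
#' @param cube A [hypercube].
#' @param lambda1,lambda2 Numerator and denominator wavelengths in nm.
#' @param epsilon Positive denominator guard; default as in
#'   [band_ratio_search()].
#' @return Matrix (lines x samples).
#' @export
ratio_image <- function(cube, lambda1, lambda2, epsilon = NULL) {
  num <- band_image(cube, lambda1)
  den <- band_image(cube, lambda2)
  if (is.null(epsilon)) epsilon <- default_epsilon(cube$data)
  num / (den + epsilon)
}

#' Otsu threshold of an image
#'
#' Canonical 256-bin histogram formulation: the threshold maximizes the
#' between-class variance of the two pixel populations it separates, with
#' pixel values represented by their bin centers. Returns the upper edge of
#' the selected bin so that `value < threshold` splits exactly at a bin
#' boundary.
#'
#' @param img Numeric matrix with at least two distinct values.
#' @param nbins Number of histogram bins (default 256).
#' @return Threshold value (scalar).
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate histogram: image is constant")
  edges <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  centers <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins)
  w <- cumsum(counts)
  mu <- cumsum(counts * centers)
  n <- w[nbins]; mu_t <- mu[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- w[k]; w1 <- n - w0
  sigma_b <- ifelse(w0 > 0 & w1 > 0,
                    (n * mu[k] - mu_t * w0)^2 / (w0 * w1), -Inf)
  edges[which.max(sigma_b) + 1L]
}

#' Binary plant mask via Otsu thresholding
#'
#' @param ratio_img Ratio image (matrix).
#' @param polarity `"above"` if plant pixels exceed the threshold (ratio
#'   higher on leaves; negative best-pair correlation with the
#'   lettuce=1/soil=2 coding), `"below"` otherwise.
#' @param provenance Optional list recorded alongside the mask (band pair
#'   etc.).
#' @param nbins Histogram bins for [otsu_threshold()].
#' @return A `plant_mask`: logical `mask` plus `provenance` with the
#'   threshold and polarity.
#' @export
otsu_mask <- function(ratio_img, polarity = c("above", "below"),
                      provenance = list(), nbins = 256L) {
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(ratio_img, nbins = nbins)
  mask <- if (polarity == "above") ratio_img >= thr else ratio_img < thr
  provenance$threshold <- thr
  provenance$polarity <- polarity
  structure(list(mask = mask, provenance = provenance), class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat(sprintf("<plant_mask> %d x %d, %d plant pixels (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  if (!is.null(x$provenance$threshold))
    cat(sprintf("  threshold %.4g, polarity %s\n",
                x$provenance$threshold, x$provenance$polarity))
  invisible(x)
}

#' Apply a binary mask to a cube or image
#'
#' Non-mask pixels are set to zero. Masking is idempotent.
#'
#' @param x A [hypercube] or matrix.
#' @param mask A `plant_mask` or logical matrix.
#' @return Same type as `x`.
#' @export
apply_mask <- function(x, mask) {
  m <- as_mask_matrix(mask)
  if (inherits(x, "hypercube")) {
    if (!all(dim(m) == dim(x$data)[1:2]))
      stop("mask shape does not match cube spatial shape")
    x$data <- x$data * as.numeric(rep(m, times = dim(x$data)[3L]))
    dim(x$data) <- c(dim(m), length(x$wavelengths))
    x
  } else {
    if (!all(dim(m) == dim(x))) stop("mask shape does not match image")
    x * m
  }
}

#' Write a plant mask as an 8-bit PNG
#'
#' @param mask A `plant_mask` or logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}
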