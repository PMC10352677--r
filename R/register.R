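# Integer-translate a matrix, zero-filling vacated pixels.
shift_matrix <- function(img, dy, dx, fill = 0) {
  d <- dim(img)
  if (abs(dy) >= d[1L] || abs(dx) >= d[2L])
    stop("shift larger than image")
  out <- matrix(fill, d[1L], d[2L])
  ys <- seq_len(d[1L] - abs(dy)); xs <- seq_len(d[2L] - abs(dx))
  src_y <- if (dy >= 0) ys else ys + abs(dy)
  dst_y <- if (dy >= 0) ys + dy else ys
  src_x <- if (dx >= 0) xs else xs + abs(dx)
  dst_x <- if (dx >= 0) xs + dx else xs
  out[dst_y, dst_x] <- img[src_y, src_x]
  out
}

#' Synthetic dot-grid calibration target
#'
#' Renders the registration target used to align reflectance and
#' fluorescence scans: a white sheet printed with a regular grid of black
#' dots.
#'
#' @param rows,cols Number of dot rows/columns.
#' @param pitch Center-to-center dot spacing in pixels.
#' @param dot_radius Dot radius in pixels (must be positive and less than
#'   `pitch / 2` so dots do not overlap).
#' @param shape Image dimensions `c(lines, samples)`.
#' @param origin Center of the first dot, default `c(pitch, pitch)`.
#' @return Matrix in [0, 1]: 1 = white paper, 0 = dot.
#' @export
make_dot_grid <- function(rows, cols, pitch, dot_radius, shape,
                          origin = c(pitch, pitch)) {
  if (dot_radius <= 0) stop("dot_radius must be positive")
  if (2 * dot_radius >= pitch) stop("overlapping dots: 2*radius must be < pitch")
  last <- origin + (c(rows, cols) - 1) * pitch
  if (origin[1L] - dot_radius < 1 || origin[2L] - dot_radius < 1 ||
      last[1L] + dot_radius > shape[1L] || last[2L] + dot_radius > shape[2L])
    stop("dot grid does not fit in image shape")
  img <- matrix(1, shape[1L], shape[2L])
  yy <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  xx <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      cy <- origin[1L] + (i - 1) * pitch
      cx <- origin[2L] + (j - 1) * pitch
      img[(yy - cy)^2 + (xx - cx)^2 <= dot_radius^2] <- 0
    }
  }
  img
}

#' Estimate the translation aligning two images
#'
#' Finds the integer shift that, applied to the moving image, best aligns it
#' with the fixed image by maximizing the normalized cross-correlation over
#' the overlap region. Reflectance (fixed) and fluorescence (moving) scans of
#' the same scene traverse the same track in opposite directions, so the
#' default search is horizontal-only; set `axis = "xy"` for a full 2-D
#' search. Ties are broken toward the smallest shift magnitude.
#'
#' @param fixed,moving Numeric matrices of identical shape.
#' @param max_shift Maximum absolute shift searched per axis (pixels).
#' @param axis `"x"` (default, horizontal-only) or `"xy"`.
#' @return A `registration_result`: `shift = c(dy, dx)` to apply to the
#'   moving image, and `score` (normalized cross-correlation clamped to
#'   [0, 1]).
#' @export
estimate_shift <- function(fixed, moving, max_shift = 20L, axis = c("x", "xy")) {
  axis <- match.arg(axis)
  if (!all(dim(fixed) == dim(moving))) stop("images must have the same shape")
  if (max_shift >= min(dim(fixed)) / 2)
    stop("max_shift must be below half the smaller image dimension")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("no features: constant image")
  dys <- if (axis == "x") 0L else seq(-max_shift, max_shift)
  dxs <- seq(-max_shift, max_shift)
  best <- list(r = -Inf, shift = c(0L, 0L))
  for (dy in dys) {
    for (dx in dxs) {
      # overlap of fixed with moving translated by (dy, dx)
      fy <- seq(max(1L, 1L + dy), min(nrow(fixed), nrow(fixed) + dy))
      fx <- seq(max(1L, 1L + dx), min(ncol(fixed), ncol(fixed) + dx))
      a <- fixed[fy, fx]
      b <- moving[fy - dy, fx - dx]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(as.vector(a), as.vector(b))
      better <- r > best$r + 1e-12 ||
        (abs(r - best$r) <= 1e-12 &&
           sum(abs(c(dy, dx))) < sum(abs(best$shift)))
      if (better) best <- list(r = r, shift = c(dy, dx))
    }
  }
  if (!is.finite(best$r)) stop("no features: all overlaps constant")
  structure(list(shift = as.integer(best$shift),
                 score = max(0, min(1, best$r))),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> shift (dy, dx) = (%d, %d), score %.3f\n",
              x$shift[1L], x$shift[2L], x$score))
  invisible(x)
}

#' Apply an integer translation to a cube or image
#'
#' Every band is translated identically; vacated pixels are filled with
#' `fill` (default 0) so they drop out of downstream masks.
#'
#' @param x A [hypercube] or matrix.
#' @param shift Integer `c(dy, dx)`; positive = down/right.
#' @param fill Fill value for vacated pixels.
#' @return Same type as `x`.
#' @export
apply_shift <- function(x, shift, fill = 0) {
  dy <- as.integer(shift[1L]); dx <- as.integer(shift[2L])
  if (inherits(x, "hypercube")) {
    for (b in seq_len(dim(x$data)[3L]))
      x$data[, , b] <- shift_matrix(x$data[, , b], dy, dx, fill = fill)
    x
  } else {
    shift_matrix(x, dy, dx, fill = fill)
  }
}

#' Register a fluorescence cube to a reflectance cube
#'
#' Convenience wrapper: estimates the shift between two single-band images
#' (by default R815 and the fluorescence band at 732 nm) and applies it to
#' the moving cube. A warning is raised if the two cubes record different
#' exposure times in their timestamps metadata, since the constant-speed
#' assumption then breaks down.
#'
#' @param fixed_cube Reflectance [hypercube] (fixed).
#' @param moving_cube Fluorescence [hypercube] (moving).
#' @param fixed_nm,moving_nm Wavelengths of the feature bands used.
#' @param max_shift,axis Passed to [estimate_shift()].
#' @return List: `cube` (shifted moving cube), `result`
#'   (`registration_result`).
#' @export
register_pair <- function(fixed_cube, moving_cube, fixed_nm = 815,
                          moving_nm = 732, max_shift = 20L,
                          axis = c("x", "xy")) {
  axis <- match.arg(axis)
  res <- estimate_shift(band_image(fixed_cube, fixed_nm),
                        band_image(moving_cube, moving_nm),
                        max_shift = max_shift, axis = axis)
  list(cube = apply_shift(moving_cube, res$shift), result = res)
}
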