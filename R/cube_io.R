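# ENVI data type codes supported for BIL payloads.
# 12-bit raw detector values live in 16-bit unsigned containers (type 12).
.envi_types <- list(
  "1"  = list(what = "integer", size = 1L, signed = FALSE),
  "2"  = list(what = "integer", size = 2L, signed = TRUE),
  "3"  = list(what = "integer", size = 4L, signed = TRUE),
  "4"  = list(what = "numeric", size = 4L, signed = TRUE),
  "5"  = list(what = "numeric", size = 8L, signed = TRUE),
  "12" = list(what = "integer", size = 2L, signed = FALSE))

#' Read an ENVI-style header
#'
#' Parses the plain-text header accompanying a BIL payload. Required fields:
#' `samples`, `lines`, `bands`, `interleave`, `data type`; `wavelength` is a
#' brace-delimited comma-separated list. Unknown keys are retained.
#'
#' @param path Path to the header file.
#' @return Named list of header fields (numeric where appropriate).
#' @export
read_envi_header <- function(path) {
  if (!file.exists(path)) stop("header file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # re-join multi-line { ... } blocks
  joined <- character(0); buf <- NULL
  for (ln in lines) {
    if (is.null(buf)) {
      if (grepl("\\{", ln) && !grepl("\\}", ln)) buf <- ln else joined <- c(joined, ln)
    } else {
      buf <- paste(buf, ln)
      if (grepl("\\}", ln)) { joined <- c(joined, buf); buf <- NULL }
    }
  }
  hdr <- list()
  for (ln in joined) {
    if (!grepl("=", ln)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    key <- tolower(key)
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
      suppressWarnings({
        num <- as.numeric(val)
        if (!anyNA(num)) val <- num
      })
    } else {
      suppressWarnings({
        num <- as.numeric(val)
        if (!is.na(num)) val <- num
      })
    }
    hdr[[key]] <- val
  }
  hdr
}

#' Write an ENVI-style header
#'
#' @param hdr Named list of fields; vector values are written as
#'   brace-delimited lists.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envi_header <- function(hdr, path) {
  fmt1 <- function(v) {
    if (is.numeric(v)) format(v, digits = 15, trim = TRUE, scientific = FALSE) else as.character(v)
  }
  out <- c("ENVI")
  for (key in names(hdr)) {
    v <- hdr[[key]]
    if (length(v) > 1L) {
      out <- c(out, paste0(key, " = {", paste(fmt1(v), collapse = ", "), "}"))
    } else {
      out <- c(out, paste0(key, " = ", fmt1(v)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a BIL hypercube
#'
#' Reads a band-interleaved-by-line binary payload with an ENVI-style text
#' header into a [hypercube]. On disk BIL stores, for each scan line, all
#' bands of that line (samples fastest); in memory the cube is reordered to
#' the analysis-friendly (line, sample, band) axis order.
#'
#' @param path Path to the binary payload.
#' @param header_path Path to the header; defaults to `paste0(path, ".hdr")`.
#' @return A [hypercube].
#' @export
read_bil <- function(path, header_path = paste0(path, ".hdr")) {
  hdr <- read_envi_header(header_path)
  for (f in c("samples", "lines", "bands", "interleave", "data type"))
    if (is.null(hdr[[f]])) stop("header missing required field: ", f)
  if (tolower(hdr$interleave) != "bil")
    stop("unsupported interleave '", hdr$interleave, "': only BIL is supported")
  ty <- .envi_types[[as.character(hdr[["data type"]])]]
  if (is.null(ty)) stop("unsupported data type code: ", hdr[["data type"]])
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines); nb <- as.integer(hdr$bands)
  n <- ns * nl * nb
  expected <- n * ty$size
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop("corrupt BIL file: payload is ", actual, " bytes, header declares ",
         expected)
  endian <- if (!is.null(hdr[["byte order"]]) && hdr[["byte order"]] == 1) "big" else "little"
  con <- file(path, "rb"); on.exit(close(con))
  raw_vals <- readBin(con, what = ty$what, n = n, size = ty$size,
                      signed = ty$signed, endian = endian)
  # disk order: sample fastest, then band, then line
  arr <- array(as.numeric(raw_vals), dim = c(ns, nb, nl))
  data <- aperm(arr, c(3L, 1L, 2L))
  wl <- hdr$wavelength
  if (is.null(wl)) wl <- seq_len(nb)
  modality <- if (!is.null(hdr$modality)) hdr$modality else "raw"
  res <- c(if (!is.null(hdr[["y resolution"]])) hdr[["y resolution"]] else NA_real_,
           if (!is.null(hdr[["x resolution"]])) hdr[["x resolution"]] else NA_real_)
  hypercube(data, wl, modality = modality,
            timestamp = if (!is.null(hdr$timestamp)) hdr$timestamp else NULL,
            resolution = res)
}

#' Write a BIL hypercube
#'
#' @param cube A [hypercube].
#' @param path Output payload path; the header goes to `header_path`.
#' @param header_path Header path, default `paste0(path, ".hdr")`.
#' @param data_type ENVI data type code: `"1"` (uint8), `"2"` (int16), `"3"`
#'   (int32), `"4"` (float32), `"5"` (float64, default), `"12"` (uint16,
#'   the container for 12-bit raw counts).
#' @param byte_order 0 little-endian (default), 1 big-endian.
#' @return `path`, invisibly.
#' @export
write_bil <- function(cube, path, header_path = paste0(path, ".hdr"),
                      data_type = "5", byte_order = 0) {
  data_type <- as.character(data_type)
  ty <- .envi_types[[data_type]]
  if (is.null(ty)) stop("unsupported data type code: ", data_type)
  d <- dim(cube$data)
  vals <- as.vector(aperm(cube$data, c(2L, 3L, 1L)))  # sample, band, line
  endian <- if (byte_order == 1) "big" else "little"
  if (ty$what == "integer") {
    if (any(vals != round(vals)))
      stop("non-integer values cannot be written with data type ", data_type)
    lim <- switch(data_type, "1" = c(0, 255), "2" = c(-32768, 32767),
                  "12" = c(0, 65535), "3" = c(-2^31, 2^31 - 1))
    if (any(vals < lim[1L] | vals > lim[2L]))
      stop("values out of range for data type ", data_type)
    vals <- as.integer(vals)
  }
  con <- file(path, "wb")
  writeBin(vals, con, size = ty$size, endian = endian)
  close(con)
  hdr <- list(samples = d[2L], lines = d[1L], bands = d[3L],
              `header offset` = 0, `data type` = as.numeric(data_type),
              interleave = "bil", `byte order` = byte_order,
              wavelength = cube$wavelengths, modality = cube$modality)
  if (!is.null(cube$timestamp)) hdr$timestamp <- cube$timestamp
  if (!all(is.na(cube$resolution))) {
    hdr[["y resolution"]] <- cube$resolution[1L]
    hdr[["x resolution"]] <- cube$resolution[2L]
  }
  write_envi_header(hdr, header_path)
  invisible(path)
}
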