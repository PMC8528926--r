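#' Minimal grayscale TIFF input/output
#'
#' Baseline, uncompressed, single-image, little-endian TIFF with one sample
#' per pixel. This covers the package's own exports (16-bit channel rasters,
#' 32-bit float ratio maps, integer label maps) and typical single-channel
#' microscope exports saved without compression. It is not a general TIFF
#' reader: compressed, tiled, paletted or multi-page files are rejected with
#' an informative error.
#'
#' @param path file path.
#' @param image numeric or integer matrix; rows are image rows.
#' @param type `"uint16"` (default), `"uint8"` or `"float32"`.
#' @return `read_tiff()` returns a numeric matrix; `write_tiff()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' m <- matrix(0:65535, 256, 256)[1:32, 1:32]
#' write_tiff(m, f)
#' all.equal(read_tiff(f), m * 1.0)
#' @name tiff_io
NULL

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' @rdname tiff_io
#' @export
write_tiff <- function(image, path, type = c("uint16", "uint8", "float32")) {
  type <- match.arg(type)
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  bps <- switch(type, uint8 = 1L, uint16 = 2L, float32 = 4L)
  fmt <- switch(type, uint8 = 1L, uint16 = 1L, float32 = 3L)
  vals <- as.vector(t(image))             # TIFF stores rows contiguously
  if (type != "float32") {
    vals <- as.integer(round(vals))
    top <- if (type == "uint16") 65535L else 255L
    if (any(vals < 0L | vals > top))
      stop("values out of range for ", type, " TIFF; rescale first")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  data_bytes <- H * W * bps
  ifd_offset <- 8L + data_bytes
  writeChar("II", con, nchars = 2, eos = NULL)
  wr2(42L); wr4(ifd_offset)
  if (type == "float32") {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  } else {
    writeBin(vals, con, size = bps, endian = "little")
  }
  entry <- function(tag, typ, count, value) { wr2(tag); wr2(typ); wr4(count); wr4(value) }
  wr2(9L)  # number of IFD entries
  entry(TIFF_TAGS[["width"]], 4L, 1L, W)
  entry(TIFF_TAGS[["height"]], 4L, 1L, H)
  entry(TIFF_TAGS[["bits"]], 3L, 1L, 8L * bps)
  entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
  entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
  entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, 8L)
  entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
  entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, data_bytes)
  entry(TIFF_TAGS[["sample_format"]], 3L, 1L, fmt)
  wr4(0L)  # no further IFD
  invisible(path)
}

read_ifd_value <- function(raw_entry, endian) {
  typ <- readBin(raw_entry[3:4], "integer", size = 2, signed = FALSE, endian = endian)
  count <- readBin(raw_entry[5:8], "integer", size = 4, endian = endian)
  if (count == 1L && typ %in% c(3L, 4L)) {
    size <- if (typ == 3L) 2L else 4L
    readBin(raw_entry[9:(8 + size)], "integer", size = size,
            signed = size > 2L, endian = endian)
  } else {
    # value stored out of line; return the offset for the caller to chase
    structure(readBin(raw_entry[9:12], "integer", size = 4, endian = endian),
              offset = TRUE, count = count, typ = typ)
  }
}

#' @rdname tiff_io
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  ifd_off <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  n_entries <- readBin(raw[ifd_off + 1:2], "integer", size = 2,
                       signed = FALSE, endian = endian)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- raw[ifd_off + 2L + (k - 1L) * 12L + 1:12]
    tag <- readBin(e[1:2], "integer", size = 2, signed = FALSE, endian = endian)
    tags[[as.character(tag)]] <- list(entry = e, value = read_ifd_value(e, endian))
  }
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v$value
  }
  read_array <- function(tag, default = NULL) {
    v <- g(tag, default)
    if (is.null(attr(v, "offset"))) return(v)
    cnt <- attr(v, "count"); typ <- attr(v, "typ")
    size <- if (typ == 3L) 2L else 4L
    readBin(raw[v + seq_len(cnt * size)], "integer", n = cnt, size = size,
            signed = size > 2L, endian = endian)
  }
  W <- g(TIFF_TAGS[["width"]]); H <- g(TIFF_TAGS[["height"]])
  if (is.null(W) || is.null(H)) stop("TIFF missing dimensions: ", path)
  if (g(TIFF_TAGS[["compression"]], 1L) != 1L)
    stop("compressed TIFF not supported: ", path)
  if (g(TIFF_TAGS[["spp"]], 1L) != 1L)
    stop("multi-sample TIFF not supported: ", path)
  bits <- read_array(TIFF_TAGS[["bits"]], 1L)[1]
  fmt <- g(TIFF_TAGS[["sample_format"]], 1L)
  offsets <- read_array(TIFF_TAGS[["strip_offsets"]])
  counts <- read_array(TIFF_TAGS[["strip_bytes"]], H * W * bits %/% 8L)
  payload <- raw(0)
  for (k in seq_along(offsets))
    payload <- c(payload, raw[offsets[k] + seq_len(counts[k])])
  n <- H * W
  vals <- if (fmt == 3L) {
    readBin(payload, "double", n = n, size = 4, endian = endian)
  } else if (bits == 8L) {
    as.numeric(readBin(payload, "integer", n = n, size = 1, signed = FALSE,
                       endian = endian))
  } else if (bits == 16L) {
    as.numeric(readBin(payload, "integer", n = n, size = 2, signed = FALSE,
                       endian = endian))
  } else if (bits == 32L) {
    as.numeric(readBin(payload, "integer", n = n, size = 4, endian = endian))
  } else stop("unsupported bit depth ", bits, ": ", path)
  matrix(vals, nrow = H, ncol = W, byrow = TRUE)
}
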