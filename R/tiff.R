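#' Minimal grayscale TIFF input/output
#'
#' Baseline TIFF codec for the single-plane grayscale images this pipeline
#' exchanges: unsigned 8/16-bit integer rasters (raw camera counts, label
#' maps) and 32-bit float rasters (illumination profiles).  Data are stored
#' uncompressed; both single- and multi-strip files are read.  This exists
#' because the deployment environment provides no R TIFF reader; the format
#' emitted is deliberately the smallest valid baseline subset and has been
#' validated against an independent TIFF implementation.
#'
#' Images are R matrices in row/column orientation: `img[r, c]` is the pixel
#' at 0-based row `r - 1`, column `c - 1` of the raster.
#'
#' @param img numeric or integer matrix (rows x cols).
#' @param path file path.
#' @param type `"uint8"`, `"uint16"` or `"float"`.
#' @return `read_tiff()` returns a numeric matrix; `write_tiff()` returns
#'   `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".tif")
#' m <- matrix(0:11, 3, 4)
#' write_tiff(m, p)
#' stopifnot(identical(read_tiff(p), m + 0))
#' @export
write_tiff <- function(img, path, type = c("uint16", "uint8", "float")) {
  type <- match.arg(type)
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float = 32L)
  fmt <- switch(type, uint8 = 1L, uint16 = 1L, float = 3L)
  bytes_px <- bits %/% 8L
  data_off <- 8L
  n_bytes <- nr * nc * bytes_px
  ifd_off <- data_off + n_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  # pixel data, row-major
  v <- as.vector(t(img))
  if (type == "float") {
    writeBin(as.double(v), con, size = 4, endian = "little")
  } else {
    v <- as.integer(round(v))
    top <- 2^bits - 1
    if (any(v < 0 | v > top)) stop("pixel values out of range for ", type)
    writeBin(v, con, size = bytes_px, endian = "little")
  }
  entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == 3L) { # SHORT, pad to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(8L, con, size = 2, endian = "little") # entry count
  entry(256, 4, 1, nc)           # ImageWidth
  entry(257, 4, 1, nr)           # ImageLength
  entry(258, 3, 1, bits)         # BitsPerSample
  entry(259, 3, 1, 1)            # Compression = none
  entry(262, 3, 1, 1)            # Photometric = BlackIsZero
  entry(273, 4, 1, data_off)     # StripOffsets
  entry(279, 4, 1, n_bytes)      # StripByteCounts
  entry(339, 3, 1, fmt)          # SampleFormat
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  bo <- rawToChar(raw[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1) {
    # readBin only supports unsigned reads for sizes 1-2; TIFF LONGs of
    # interest here (offsets, dims) fit in a signed 32-bit int anyway
    readBin(raw[(off + 1):(off + size * n)], "integer",
            n = n, size = size, endian = endian, signed = size >= 4)
  }
  if (rint(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rint(4, 4)
  n_ent <- rint(ifd, 2)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)
  for (i in seq_len(n_ent)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rint(e, 2); typ <- rint(e + 2, 2); cnt <- rint(e + 4, 4)
    sz <- type_size[as.character(typ)]
    vals <- if (!is.na(sz) && sz * cnt <= 4) {
      rint(e + 8, sz, cnt)
    } else if (!is.na(sz)) {
      rint(rint(e + 8, 4), sz, cnt)
    } else NULL
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  wd <- need(256); ht <- need(257)
  bits <- need(258, 1L)[1]
  comp <- need(259, 1L)
  spp <- need(277, 1L)
  fmt <- need(339, 1L)[1]
  if (comp != 1L) stop("only uncompressed TIFF supported: ", path)
  if (spp != 1L) stop("only single-sample (grayscale) TIFF supported: ", path)
  offs <- need(273)
  counts <- need(279, as.integer(wd * ht * bits / 8))
  bytes_px <- bits %/% 8L
  px <- numeric(0)
  for (s in seq_along(offs)) {
    npx <- counts[s] %/% bytes_px
    seg <- raw[(offs[s] + 1):(offs[s] + counts[s])]
    px <- c(px, if (fmt == 3L) {
      readBin(seg, "double", n = npx, size = 4, endian = endian)
    } else if (bits == 32L) {
      readBin(seg, "integer", n = npx, size = 4, endian = endian)
    } else {
      readBin(seg, "integer", n = npx, size = bytes_px,
              endian = endian, signed = FALSE)
    })
  }
  if (length(px) != wd * ht) stop("TIFF pixel count mismatch in ", path)
  t(matrix(px, nrow = wd, ncol = ht))
}
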