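## Minimal baseline TIFF 6.0 support for lambda stacks.
##
## No TIFF package is available in the target environment, so the subset the
## pipeline needs is implemented here: single-sample (grayscale) images,
## uncompressed, one or more strips, uint8/16/32 or float32/64 samples,
## little- or big-endian files, multi-page. The writer always emits
## little-endian single-strip pages. Anything fancier (compression, tiles,
## palettes, RGB) is rejected with a clear error.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8) # TIFF field types 1..12

read_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "little") b <- rev(b)
  v <- 0
  for (x in b) v <- v * 256 + x
  v
}

#' Read a multi-page grayscale TIFF into an array
#'
#' Supports the uncompressed baseline subset used for lambda stacks: one
#' sample per pixel, 8/16/32-bit unsigned integer or 32/64-bit float data,
#' either byte order, any strip layout.
#'
#' @param path TIFF file path.
#' @return Numeric array `[height, width, pages]`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file (too short): ", path, call. = FALSE)
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte order mark): ", path,
                        call. = FALSE))
  if (read_uint(raw, 2, 2, endian) != 42)
    stop("not a TIFF file (bad magic): ", path, call. = FALSE)

  dec <- function(off, size) read_uint(raw, off, size, endian)
  pages <- list()
  ifd <- dec(4, 4)
  while (ifd != 0) {
    n <- dec(ifd, 2)
    tags <- list()
    for (i in seq_len(n) - 1L) {
      e <- ifd + 2 + 12 * i
      tag <- dec(e, 2); type <- dec(e + 2, 2); count <- dec(e + 4, 4)
      tsz <- if (type >= 1 && type <= 12) TIFF_TYPE_SIZES[type] else 1
      nbytes <- tsz * count
      voff <- if (nbytes <= 4) e + 8 else dec(e + 8, 4)
      vals <- if (type %in% c(3, 4, 1)) {
        vapply(seq_len(count) - 1L, function(j) dec(voff + j * tsz, tsz),
               numeric(1))
      } else NULL
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h))
      stop("TIFF page missing dimensions", call. = FALSE)
    if (g(259, 1) != 1)
      stop("only uncompressed TIFF is supported (Compression tag = ",
           g(259), ")", call. = FALSE)
    if (g(277, 1) != 1)
      stop("only single-sample (grayscale) TIFF is supported", call. = FALSE)
    bits <- g(258, 1)
    fmt <- g(339, 1) # 1 = unsigned int, 3 = IEEE float
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF page missing strip offsets", call. = FALSE)
    if (is.null(counts)) counts <- rep(w * h * bits / 8 / length(offsets),
                                       length(offsets))
    data_raw <- raw[unlist(lapply(seq_along(offsets), function(i)
      offsets[i] + seq_len(counts[i])))]
    npix <- w * h
    vals <- if (fmt == 3) {
      readBin(data_raw, "double", n = npix, size = bits / 8, endian = endian)
    } else if (fmt == 1) {
      if (bits == 32) {
        v <- readBin(data_raw, "integer", n = npix, size = 4, endian = endian)
        v <- as.numeric(v); v[v < 0] <- v[v < 0] + 2^32; v
      } else {
        as.numeric(readBin(data_raw, "integer", n = npix, size = bits / 8,
                           signed = FALSE, endian = endian))
      }
    } else stop("unsupported TIFF sample format: ", fmt, call. = FALSE)
    if (length(vals) != npix)
      stop("TIFF strip data truncated", call. = FALSE)
    # strips store rows top-to-bottom, pixels left-to-right (row-major)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- dec(ifd + 2 + 12 * n, 4)
  }
  if (length(pages) == 0) stop("TIFF file contains no images", call. = FALSE)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have differing dimensions", call. = FALSE)
  array(unlist(pages), dim = c(dims[1, 1], dims[2, 1], length(pages)))
}

#' Write an array as a multi-page grayscale TIFF
#'
#' Emits uncompressed little-endian pages, one strip per page.
#'
#' @param x Numeric array `[height, width]` or `[height, width, pages]`.
#' @param path Output path.
#' @param dtype Sample type: `"float32"` (default; lossless for photon-count
#'   scale data), `"float64"`, `"uint8"`, `"uint16"` or `"uint32"`.
#' @export
write_tiff <- function(x, path,
                       dtype = c("float32", "float64", "uint8", "uint16",
                                 "uint32")) {
  dtype <- match.arg(dtype)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3)
  h <- dim(x)[1]; w <- dim(x)[2]; npg <- dim(x)[3]
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, uint32 = 32L,
                 float32 = 32L, float64 = 64L)
  fmt <- if (startsWith(dtype, "float")) 3L else 1L
  bytes_per_page <- w * h * bits / 8

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42)
  # layout per page: [strip data][IFD]; header points at first IFD
  n_entries <- 10L
  ifd_size <- 2 + 12 * n_entries + 4
  page_size <- bytes_per_page + ifd_size
  first_ifd <- 8 + bytes_per_page
  w32(first_ifd)

  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3) { w16(value); w16(0) } else w32(value)
  }
  for (p in seq_len(npg)) {
    strip_off <- 8 + (p - 1) * page_size
    vals <- as.vector(t(x[, , p])) # row-major
    if (fmt == 1) {
      maxv <- 2^bits - 1
      iv <- round(vals)
      if (any(iv < 0 | iv > maxv))
        stop(sprintf("values outside [0, %.0f] cannot be stored as %s",
                     maxv, dtype), call. = FALSE)
      if (bits == 32) {
        iv[iv > .Machine$integer.max] <- iv[iv > .Machine$integer.max] - 2^32
        writeBin(as.integer(iv), con, size = 4, endian = "little")
      } else {
        writeBin(as.integer(iv), con, size = bits / 8, endian = "little")
      }
    } else {
      writeBin(as.numeric(vals), con, size = bits / 8, endian = "little")
    }
    w16(n_entries) # tag order must be ascending
    entry(256, 4, 1, w); entry(257, 4, 1, h)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)       # no compression
    entry(262, 3, 1, 1)       # black is zero
    entry(273, 4, 1, strip_off)
    entry(277, 3, 1, 1)       # one sample per pixel
    entry(278, 4, 1, h)       # single strip
    entry(279, 4, 1, bytes_per_page)
    entry(339, 3, 1, fmt)
    w32(if (p < npg) 8 + p * page_size + bytes_per_page else 0)
  }
  invisible(path)
}
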