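# Minimal multi-page TIFF codec (baseline grayscale, uncompressed).
#
# No TIFF package ships with the supported toolchain, so the subset this
# package needs is implemented directly: single-sample grayscale pages,
# compression = none, strip-organized, uint8/uint16/uint32 and float32
# samples. The reader accepts both byte orders and multi-strip layouts
# (enough to round-trip files written by common scientific writers); the
# writer emits little-endian float32 or uint16, one strip per page.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_uint <- function(con, size, endian, n = 1L) {
  v <- readBin(con, "integer", n = n, size = size, signed = size >= 4L,
               endian = endian)
  if (size == 4L) v[v < 0] <- v[v < 0] + 2^32
  v
}

tiff_read_values <- function(raw_bytes, type, count, endian) {
  con <- rawConnection(raw_bytes)
  on.exit(close(con))
  if (type %in% c(1L, 6L, 7L)) {
    readBin(con, "integer", n = count, size = 1L, signed = type == 6L)
  } else if (type %in% c(3L, 8L)) {
    readBin(con, "integer", n = count, size = 2L, signed = type == 8L,
            endian = endian)
  } else if (type %in% c(4L, 9L)) {
    read_uint(con, 4L, endian, n = count)
  } else if (type == 11L) {
    readBin(con, "numeric", n = count, size = 4L, endian = endian)
  } else if (type == 12L) {
    readBin(con, "numeric", n = count, size = 8L, endian = endian)
  } else if (type == 5L) {
    v <- read_uint(con, 4L, endian, n = 2L * count)
    v[seq(1, 2 * count, 2)] / v[seq(2, 2 * count, 2)]
  } else {
    rep(NA_real_, count)
  }
}

#' Read a grayscale multi-page TIFF
#'
#' Supports baseline uncompressed single-sample TIFFs (8/16/32-bit unsigned
#' integer or 32-bit float), either byte order, strip-organized.
#'
#' @param path file path.
#' @return a list of numeric matrices (rows = image rows), one per page, with
#'   attributes `bits` and `sample_format` from the first page.
#' @export
read_tiff <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("cannot read TIFF: file not found: ", path)
  buf <- readBin(path, "raw", n = sz)
  order_tag <- rawToChar(buf[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark)"))
  con <- rawConnection(buf)
  on.exit(close(con))
  seek(con, 2)
  magic <- read_uint(con, 2L, endian)
  if (magic != 42L) stop("not a TIFF file (bad magic number)")
  ifd_offset <- read_uint(con, 4L, endian)
  pages <- list()
  while (ifd_offset != 0) {
    seek(con, ifd_offset)
    n_entries <- read_uint(con, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- read_uint(con, 2L, endian)
      type <- read_uint(con, 2L, endian)
      count <- read_uint(con, 4L, endian)
      nbytes <- TIFF_TYPE_SIZE[[as.character(type)]] %||% 1L
      nbytes <- nbytes * count
      value_field <- readBin(con, "raw", n = 4L)
      if (nbytes > 4L) {
        voff <- tiff_read_values(value_field, 4L, 1L, endian)
        raw_vals <- buf[(voff + 1):(voff + nbytes)]
      } else {
        raw_vals <- value_field[seq_len(max(nbytes, 1L))]
      }
      tags[[as.character(tag)]] <- tiff_read_values(raw_vals, type, count, endian)
    }
    next_ifd <- read_uint(con, 4L, endian)

    gettag <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    width <- gettag(256); height <- gettag(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bits <- gettag(258, 1L)[1]
    compression <- gettag(259, 1L)[1]
    if (compression != 1L) {
      stop("unsupported TIFF compression scheme ", compression,
           " (only uncompressed is supported)")
    }
    spp <- gettag(277, 1L)[1]
    if (spp != 1L) stop("only single-sample (grayscale) TIFFs are supported")
    fmt <- gettag(339, 1L)[1]
    strip_offsets <- gettag(273)
    strip_counts <- gettag(279)
    rows_per_strip <- gettag(278, height)[1]
    if (is.null(strip_offsets)) stop("TIFF page missing strip offsets")
    if (is.null(strip_counts)) {
      strip_counts <- rep(rows_per_strip * width * bits / 8, length(strip_offsets))
    }
    vals <- numeric(width * height)
    pos <- 1L
    for (s in seq_along(strip_offsets)) {
      sc <- rawConnection(buf[(strip_offsets[s] + 1):(strip_offsets[s] + strip_counts[s])])
      n_here <- strip_counts[s] / (bits / 8)
      v <- if (fmt == 3L) {
        readBin(sc, "numeric", n = n_here, size = bits / 8, endian = endian)
      } else if (bits == 8L) {
        readBin(sc, "integer", n = n_here, size = 1L, signed = FALSE)
      } else if (bits == 16L) {
        readBin(sc, "integer", n = n_here, size = 2L, signed = FALSE, endian = endian)
      } else if (bits == 32L) {
        read_uint(sc, 4L, endian, n = n_here)
      } else {
        close(sc); stop("unsupported TIFF bit depth ", bits)
      }
      close(sc)
      vals[pos:(pos + n_here - 1)] <- v
      pos <- pos + as.integer(n_here)
    }
    m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    pages[[length(pages) + 1L]] <- m
    attr(pages[[length(pages)]], "bits") <- bits
    attr(pages[[length(pages)]], "sample_format") <- fmt
    ifd_offset <- next_ifd
  }
  if (!length(pages)) stop("TIFF file contains no pages")
  pages
}

#' Write a grayscale multi-page TIFF
#'
#' Writes little-endian, uncompressed, one strip per page.
#'
#' @param path output path.
#' @param pages a numeric matrix, a list of matrices, or a 3D array
#'   `[row, col, page]`.
#' @param format `"float32"` (default; computed images can be negative) or
#'   `"uint16"` (values are rounded and clipped to 0..65535).
#' @return the path, invisibly.
#' @export
write_tiff <- function(path, pages, format = c("float32", "uint16")) {
  format <- match.arg(format)
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3) {
    pages <- lapply(seq_len(dim(pages)[3]), function(i) pages[, , i])
  }
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  bits <- 32L
  fmt_code <- if (format == "float32") 3L else 1L
  if (format == "uint16") bits <- 16L
  con <- file(path, "wb")
  on.exit(close(con))
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_u32 <- function(v) for (x in v) {
    if (x >= 2^31) x <- x - 2^32
    writeBin(as.integer(x), con, size = 4L, endian = "little")
  }
  writeBin(charToRaw("II"), con); w_u16(42L)
  n <- length(pages)
  header_len <- 8L
  strip_sizes <- vapply(pages, function(p) length(p) * bits / 8L, numeric(1))
  strip_offsets <- header_len + cumsum(c(0, strip_sizes[-n]))
  ifd_len <- 2L + 10L * 12L + 4L
  ifd_offsets <- header_len + sum(strip_sizes) + (seq_len(n) - 1L) * ifd_len
  w_u32(ifd_offsets[1])
  for (p in pages) {
    v <- as.vector(t(p))  # row-major
    if (format == "float32") {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    } else {
      v <- pmin(pmax(round(v), 0), 65535)
      iv <- as.integer(v)
      iv[iv >= 2^15] <- iv[iv >= 2^15] - 65536L
      writeBin(iv, con, size = 2L, endian = "little")
    }
  }
  entry <- function(tag, type, count, value) {
    w_u16(tag); w_u16(type); w_u32(count)
    if (type == 3L) { w_u16(value); w_u16(0L) } else w_u32(value)
  }
  for (i in seq_len(n)) {
    d <- dim(pages[[i]])
    w_u16(10L)
    entry(256L, 4L, 1L, d[2])              # ImageWidth
    entry(257L, 4L, 1L, d[1])              # ImageLength
    entry(258L, 3L, 1L, bits)              # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression = none
    entry(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
    entry(273L, 4L, 1L, strip_offsets[i])  # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, d[1])              # RowsPerStrip
    entry(279L, 4L, 1L, strip_sizes[i])    # StripByteCounts
    entry(339L, 3L, 1L, fmt_code)          # SampleFormat
    w_u32(if (i < n) ifd_offsets[i + 1] else 0L)
  }
  invisible(path)
}
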