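# Minimal self-contained image codecs.
#
# No TIFF/PNG reader is available among the package's allowed dependencies,
# so the two on-disk dialects of the mask-stack contract are implemented
# here directly: uncompressed multi-page grayscale TIFF (the canonical
# format, 8/16-bit unsigned) and grayscale PNG (8/16-bit, zlib streams via
# base memCompress/memDecompress, CRC32 and scanline unfiltering in C++).
# Both are lossless integer codecs; round trips are bit-exact.

# ---- little/big-endian raw helpers ----------------------------------------

u16_raw <- function(x, big = FALSE) {
  lo <- as.raw(x %% 256L); hi <- as.raw(x %/% 256L)
  if (big) as.vector(rbind(hi, lo)) else as.vector(rbind(lo, hi))
}

u32_raw <- function(x, big = FALSE) {
  b0 <- as.raw(x %% 256); x <- x %/% 256
  b1 <- as.raw(x %% 256); x <- x %/% 256
  b2 <- as.raw(x %% 256); b3 <- as.raw(x %/% 256)
  if (big) as.vector(rbind(b3, b2, b1, b0)) else as.vector(rbind(b0, b1, b2, b3))
}

raw_u16 <- function(r, big = FALSE) {
  v <- as.integer(r)
  i <- seq(1L, length(v), by = 2L)
  if (big) v[i] * 256L + v[i + 1L] else v[i] + v[i + 1L] * 256L
}

raw_u32 <- function(r, big = FALSE) {
  v <- as.double(as.integer(r))
  i <- seq(1, length(v), by = 4)
  if (big) ((v[i] * 256 + v[i + 1]) * 256 + v[i + 2]) * 256 + v[i + 3]
  else ((v[i + 3] * 256 + v[i + 2]) * 256 + v[i + 1]) * 256 + v[i]
}

# ---- TIFF ------------------------------------------------------------------

# Write a list of integer matrices as an uncompressed multi-page grayscale
# TIFF (little-endian, one strip per page).
write_tiff_stack <- function(frames, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  maxval <- if (bits == 8L) 255L else 65535L
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  bpp <- bits / 8L
  n <- length(frames)
  ifd_size <- 2L + 10L * 12L + 4L
  data_size <- as.integer(w * h * bpp)
  pad <- data_size %% 2L                      # keep IFDs word-aligned
  con <- file(path, "wb")
  on.exit(close(con))
  # header: II, 42, offset of first IFD (follows first page's pixel data)
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)
  writeBin(u16_raw(42L), con)
  writeBin(u32_raw(8 + data_size + pad), con)
  offset <- 8
  for (p in seq_len(n)) {
    m <- frames[[p]]
    if (nrow(m) != h || ncol(m) != w)
      st_stop("all frames must share identical dimensions", "dimension_error")
    v <- as.integer(t(m))
    if (anyNA(v) || any(v < 0L) || any(v > maxval))
      st_stop("pixel values out of range for %d-bit TIFF", "format_error", bits)
    if (bits == 8L) writeBin(as.raw(v), con) else writeBin(u16_raw(v), con)
    if (pad) writeBin(as.raw(0L), con)
    data_offset <- offset
    ifd_offset <- offset + data_size + pad
    next_ifd <- if (p < n) ifd_offset + ifd_size + data_size + pad else 0
    entry <- function(tag, type, count, value)
      c(u16_raw(tag), u16_raw(type), u32_raw(count),
        if (type == 3L) c(u16_raw(value), u16_raw(0L)) else u32_raw(value))
    ifd <- c(
      u16_raw(10L),
      entry(256L, 4L, 1L, w),                 # ImageWidth
      entry(257L, 4L, 1L, h),                 # ImageLength
      entry(258L, 3L, 1L, bits),              # BitsPerSample
      entry(259L, 3L, 1L, 1L),                # Compression = none
      entry(262L, 3L, 1L, 1L),                # Photometric = BlackIsZero
      entry(273L, 4L, 1L, data_offset),       # StripOffsets
      entry(277L, 3L, 1L, 1L),                # SamplesPerPixel
      entry(278L, 4L, 1L, h),                 # RowsPerStrip
      entry(279L, 4L, 1L, data_size),         # StripByteCounts
      entry(339L, 3L, 1L, 1L),                # SampleFormat = unsigned
      u32_raw(next_ifd)
    )
    writeBin(ifd, con)
    offset <- ifd_offset + ifd_size
  }
  invisible(path)
}

# Read an uncompressed grayscale TIFF (single- or multi-page, 8/16-bit,
# little- or big-endian) into a list of integer matrices.
read_tiff_stack <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 8) st_stop("not a TIFF file: %s", "format_error", path)
  big <- if (r[1] == as.raw(0x4d)) TRUE else FALSE
  if (raw_u16(r[3:4], big) != 42L)
    st_stop("not a TIFF file: %s", "format_error", path)
  ifd_off <- raw_u32(r[5:8], big)
  frames <- list()
  while (ifd_off != 0) {
    nent <- raw_u16(r[ifd_off + 1:2], big)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- raw_u16(r[base + 1:2], big)
      type <- raw_u16(r[base + 3:4], big)
      count <- raw_u32(r[base + 5:8], big)
      tsize <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      nbytes <- tsize * count
      vals_raw <- if (nbytes <= 4) r[base + 8 + seq_len(nbytes)]
                  else r[raw_u32(r[base + 9:12], big) + seq_len(nbytes)]
      vals <- switch(as.character(type),
        "1" = as.integer(vals_raw),
        "3" = raw_u16(vals_raw, big),
        "4" = raw_u32(vals_raw, big),
        NULL)
      tags[[as.character(tag)]] <- vals
    }
    get_tag <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- get_tag(256); h <- get_tag(257)
    if (is.null(w) || is.null(h))
      st_stop("TIFF page missing dimensions", "format_error")
    bits <- get_tag(258, 1L)[1]
    if (!bits %in% c(8, 16))
      st_stop("unsupported TIFF bit depth %d", "format_error", bits)
    if (get_tag(259, 1L)[1] != 1)
      st_stop("only uncompressed TIFF is supported", "format_error")
    offs <- get_tag(273); cnts <- get_tag(279)
    if (is.null(offs) || is.null(cnts))
      st_stop("TIFF page missing strip layout", "format_error")
    data <- raw(sum(cnts))
    pos <- 0
    for (s in seq_along(offs)) {
      data[pos + seq_len(cnts[s])] <- r[offs[s] + seq_len(cnts[s])]
      pos <- pos + cnts[s]
    }
    v <- if (bits == 8) as.integer(data) else raw_u16(data, big)
    if (length(v) != w * h)
      st_stop("TIFF pixel data size mismatch", "format_error")
    frames[[length(frames) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    next_off <- ifd_off + 2 + nent * 12
    ifd_off <- raw_u32(r[next_off + 1:4], big)
  }
  frames
}

# ---- PNG -------------------------------------------------------------------

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_raw(length(data), big = TRUE), body,
    u32_raw(cpp_crc32(body), big = TRUE))
}

# Write one integer matrix as a grayscale PNG (color type 0, 8 or 16 bit).
write_png_gray <- function(mat, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  maxval <- if (bits == 8L) 255L else 65535L
  v <- as.integer(t(mat))
  if (anyNA(v) || any(v < 0L) || any(v > maxval))
    st_stop("pixel values out of range for %d-bit PNG", "format_error", bits)
  h <- nrow(mat); w <- ncol(mat)
  bytes <- if (bits == 8L) as.raw(v) else u16_raw(v, big = TRUE)
  rowbytes <- w * bits / 8L
  scan <- raw(h * (rowbytes + 1L))
  rows <- matrix(bytes, nrow = rowbytes)          # one column per scanline
  scan_mat <- rbind(raw(h), rows)                 # filter byte 0 per row
  scan <- as.vector(scan_mat)
  idat <- memCompress(scan, "gzip")               # zlib stream
  ihdr <- c(u32_raw(w, big = TRUE), u32_raw(h, big = TRUE),
            as.raw(c(bits, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

# Read a grayscale PNG into an integer matrix.
read_png_gray <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(r) < 8 || !identical(r[1:8], sig))
    st_stop("not a PNG file: %s", "format_error", path)
  pos <- 8
  idat <- list(); w <- h <- bits <- NULL
  while (pos + 8 <= length(r)) {
    len <- raw_u32(r[pos + 1:4], big = TRUE)
    type <- rawToChar(r[pos + 5:8])
    data <- if (len > 0) r[pos + 8 + seq_len(len)] else raw(0)
    if (type == "IHDR") {
      w <- raw_u32(data[1:4], big = TRUE)
      h <- raw_u32(data[5:8], big = TRUE)
      bits <- as.integer(data[9])
      if (as.integer(data[10]) != 0L)
        st_stop("only grayscale PNG (color type 0) is supported",
                "format_error")
      if (!bits %in% c(8L, 16L))
        st_stop("unsupported PNG bit depth %d", "format_error", bits)
      if (as.integer(data[13]) != 0L)
        st_stop("interlaced PNG is not supported", "format_error")
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (is.null(w) || length(idat) == 0)
    st_stop("corrupt PNG file: %s", "format_error", path)
  scan <- memDecompress(do.call(c, idat), "gzip")
  bpp <- bits / 8L
  data <- cpp_png_unfilter(scan, h, w * bpp, bpp)
  v <- if (bits == 8L) as.integer(data) else raw_u16(data, big = TRUE)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}
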