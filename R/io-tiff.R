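# Minimal baseline TIFF I/O: 8 bits per sample, uncompressed, chunky planar
# configuration, grayscale (photometric 1) or RGB (photometric 2). Reads
# both byte orders; writes little-endian with a single strip. Compressed
# TIFFs are rejected with a clear message.

tiff_read_ifd_value <- function(bytes, entry_off, endian) {
  rint <- function(off, size, n = 1L) {
    # offsets/dimensions < 2^31 in practice, so size-4 reads may be signed
    readBin(bytes[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  }
  tag   <- rint(entry_off, 2L)
  type  <- rint(entry_off + 2L, 2L)
  count <- readBin(bytes[(entry_off + 5L):(entry_off + 8L)], "integer",
                   size = 4L, endian = endian)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
  if (is.na(size)) return(list(tag = tag, values = NULL))
  total <- size * count
  voff <- if (total <= 4L) entry_off + 8L else
    readBin(bytes[(entry_off + 9L):(entry_off + 12L)], "integer", size = 4L,
            endian = endian)
  vals <- rint(voff, size, count)
  list(tag = tag, values = vals)
}

read_tiff <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  order <- rawToChar(bytes[1:2])
  endian <- switch(order, "II" = "little", "MM" = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  magic <- readBin(bytes[3:4], "integer", size = 2L, endian = endian)
  if (magic != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_off <- readBin(bytes[5:8], "integer", size = 4L, endian = endian)
  n_entries <- readBin(bytes[(ifd_off + 1L):(ifd_off + 2L)], "integer",
                       size = 2L, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- tiff_read_ifd_value(bytes, ifd_off + 2L + (i - 1L) * 12L, endian)
    tags[[as.character(e$tag)]] <- e$values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, call. = FALSE)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 1L); comp <- need(259, 1L); photo <- need(262)
  offsets <- need(273); spp <- need(277, 1L)
  counts <- need(279); planar <- need(284, 1L)
  if (comp != 1L)
    stop("only uncompressed TIFFs are supported (compression tag ", comp, ")",
         call. = FALSE)
  if (!all(bits == 8L)) stop("only 8-bit TIFFs are supported", call. = FALSE)
  if (planar != 1L) stop("only chunky planar TIFFs are supported", call. = FALSE)
  if (!(photo %in% c(1L, 2L)))
    stop("only grayscale (min-is-black) and RGB TIFFs are supported", call. = FALSE)
  ch <- as.integer(spp)
  if (!(ch %in% c(1L, 3L))) stop("unsupported samples per pixel: ", ch, call. = FALSE)
  data <- raw(0)
  for (i in seq_along(offsets))
    data <- c(data, bytes[(offsets[i] + 1L):(offsets[i] + counts[i])])
  if (length(data) != h * w * ch)
    stop("corrupt TIFF (unexpected pixel data size): ", path, call. = FALSE)
  if (ch == 1L) {
    raster_image(matrix(as.integer(data), nrow = h, ncol = w, byrow = TRUE))
  } else {
    raster_image(aperm(array(as.integer(data), dim = c(3L, w, h)), c(3, 2, 1)))
  }
}

write_tiff <- function(img, path) {
  stopifnot(is_raster_image(img))
  h <- img$height; w <- img$width; ch <- img$channels
  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    wr16(tag); wr16(type); wr32(count); wr32(value)
  }
  n_entries <- if (ch == 1L) 9L else 10L
  ifd_off <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  extra_off <- ifd_off + ifd_size          # BitsPerSample array for RGB
  extra_size <- if (ch == 3L) 6L else 0L
  data_off <- extra_off + extra_size
  writeChar("II", con, eos = NULL); wr16(42L); wr32(ifd_off)
  wr16(n_entries)
  entry(256L, 4L, 1L, w)                            # ImageWidth
  entry(257L, 4L, 1L, h)                            # ImageLength
  if (ch == 1L) entry(258L, 3L, 1L, 8L) else entry(258L, 3L, 3L, extra_off)
  entry(259L, 3L, 1L, 1L)                           # Compression: none
  entry(262L, 3L, 1L, if (ch == 1L) 1L else 2L)     # Photometric
  entry(273L, 4L, 1L, data_off)                     # StripOffsets
  entry(277L, 3L, 1L, ch)                           # SamplesPerPixel
  entry(278L, 4L, 1L, h)                            # RowsPerStrip
  entry(279L, 4L, 1L, h * w * ch)                   # StripByteCounts
  if (ch == 3L) entry(284L, 3L, 1L, 1L)             # PlanarConfiguration
  wr32(0L)                                          # next IFD: none
  if (ch == 3L) { wr16(8L); wr16(8L); wr16(8L) }
  if (ch == 1L) {
    writeBin(as.raw(t(img$pixels)), con)
  } else {
    writeBin(as.raw(aperm(img$pixels, c(3, 2, 1))), con)
  }
  invisible(path)
}
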