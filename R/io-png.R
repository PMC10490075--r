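# Native PNG codec (8-bit grayscale and RGB, non-interlaced).
#
# The IDAT payload is a zlib stream; base R's memCompress()/memDecompress()
# with type = "gzip" read and write zlib streams directly, so no external
# imaging library is needed. Chunk CRCs use the compiled CRC-32.

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

read_u32be <- function(r) {
  sum(as.numeric(r) * c(16777216, 65536, 256, 1))
}

crc32_raw <- function(x) u32be(.cpp_crc32(x))

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, crc32_raw(body))
}

PNG_SIGNATURE <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

write_png <- function(img, path) {
  stopifnot(is_raster_image(img))
  h <- img$height; w <- img$width; ch <- img$channels
  if (ch == 1L) {
    scan <- matrix(as.raw(t(img$pixels)), nrow = w, ncol = h)
  } else {
    # channel-fastest, then column, then row = row-major interleaved RGB
    scan <- matrix(as.raw(aperm(img$pixels, c(3, 2, 1))), nrow = 3L * w, ncol = h)
  }
  raw_data <- as.vector(rbind(matrix(as.raw(0), 1, h), scan))  # filter byte 0 per row
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, if (ch == 1L) 0L else 2L, 0L, 0L, 0L)))
  idat <- memCompress(raw_data, "gzip")  # zlib stream
  out <- c(PNG_SIGNATURE,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}

paeth_predict <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

png_unfilter <- function(bytes, h, w, ch) {
  stride <- w * ch
  bpp <- ch
  mat <- matrix(as.integer(bytes), nrow = stride + 1L, ncol = h)
  filt <- mat[1L, ]
  rows <- mat[-1L, , drop = FALSE]
  prev <- integer(stride)
  for (r in seq_len(h)) {
    x <- rows[, r]
    f <- filt[r]
    if (f == 0L) {
      # none
    } else if (f == 1L) {            # sub
      for (k in seq_len(bpp)) {
        idx <- seq(k, stride, by = bpp)
        x[idx] <- Reduce(function(a, b) (a + b) %% 256L, x[idx], accumulate = TRUE)
      }
    } else if (f == 2L) {            # up
      x <- (x + prev) %% 256L
    } else if (f == 3L) {            # average
      for (i in seq_len(stride)) {
        left <- if (i > bpp) x[i - bpp] else 0L
        x[i] <- (x[i] + (left + prev[i]) %/% 2L) %% 256L
      }
    } else if (f == 4L) {            # paeth
      for (i in seq_len(stride)) {
        left <- if (i > bpp) x[i - bpp] else 0L
        ul   <- if (i > bpp) prev[i - bpp] else 0L
        x[i] <- (x[i] + paeth_predict(left, prev[i], ul)) %% 256L
      }
    } else {
      stop("unsupported PNG filter type: ", f, call. = FALSE)
    }
    rows[, r] <- x
    prev <- x
  }
  rows
}

read_png <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8L || !identical(bytes[1:8], PNG_SIGNATURE))
    stop("not a PNG file: ", path, call. = FALSE)
  pos <- 9L
  ihdr <- NULL
  idat <- list()
  while (pos + 8L <= length(bytes)) {
    len <- read_u32be(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    pos <- pos + 12L + len
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
  }
  if (is.null(ihdr)) stop("corrupt PNG (missing IHDR): ", path, call. = FALSE)
  w <- read_u32be(ihdr[1:4]); h <- read_u32be(ihdr[5:8])
  bitdepth <- as.integer(ihdr[9]); colortype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (bitdepth != 8L)
    stop("only 8-bit PNGs are supported (got bit depth ", bitdepth, ")", call. = FALSE)
  if (!colortype %in% c(0L, 2L))
    stop("only grayscale and RGB PNGs are supported (got colour type ",
         colortype, ")", call. = FALSE)
  if (interlace != 0L) stop("interlaced PNGs are not supported", call. = FALSE)
  ch <- if (colortype == 0L) 1L else 3L
  raw_data <- memDecompress(do.call(c, idat), "gzip")
  if (length(raw_data) != h * (w * ch + 1L))
    stop("corrupt PNG (unexpected pixel data size): ", path, call. = FALSE)
  rows <- png_unfilter(raw_data, h, w, ch)
  if (ch == 1L) {
    raster_image(matrix(as.integer(rows), nrow = h, ncol = w, byrow = TRUE))
  } else {
    arr <- aperm(array(as.integer(rows), dim = c(3L, w, h)), c(3, 2, 1))
    raster_image(arr)
  }
}
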