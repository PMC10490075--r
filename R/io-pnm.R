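# Binary NetPBM I/O (P5 grayscale, P6 RGB, maxval 255): a convenient
# plain-ish fixture format and a sanity cross-check for the PNG codec.

read_pnm_token <- function(con) {
  tok <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PNM header", call. = FALSE)
    if (ch == "#") {                       # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(tok)) return(tok)
    } else {
      tok <- paste0(tok, ch)
    }
  }
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P5", "P6"))
    stop("only binary PGM (P5) and PPM (P6) are supported: ", path, call. = FALSE)
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval != 255L)
    stop("unsupported PNM header (need maxval 255): ", path, call. = FALSE)
  ch <- if (magic == "P5") 1L else 3L
  bytes <- readBin(con, "raw", h * w * ch)
  if (length(bytes) != h * w * ch) stop("truncated PNM pixel data: ", path, call. = FALSE)
  if (ch == 1L) {
    raster_image(matrix(as.integer(bytes), nrow = h, ncol = w, byrow = TRUE))
  } else {
    arr <- aperm(array(as.integer(bytes), dim = c(3L, w, h)), c(3, 2, 1))
    raster_image(arr)
  }
}

write_pnm <- function(img, path) {
  stopifnot(is_raster_image(img))
  con <- file(path, "wb")
  on.exit(close(con))
  magic <- if (img$channels == 1L) "P5" else "P6"
  writeChar(sprintf("%s\n%d %d\n255\n", magic, img$width, img$height), con,
            eos = NULL)
  if (img$channels == 1L) {
    writeBin(as.raw(t(img$pixels)), con)
  } else {
    writeBin(as.raw(aperm(img$pixels, c(3, 2, 1))), con)
  }
  invisible(path)
}
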