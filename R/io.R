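#' Load a raster image
#'
#' Reads a PNG, PGM/PPM, or uncompressed baseline TIFF file into a
#' [raster_image()]. Intensities are preserved bit-exactly (all supported
#' formats are lossless). Colour files load with channels ordered (R, G, B);
#' grayscale files load as 1-channel images.
#'
#' JPEG is not supported by this build: the package carries its own codecs
#' to stay free of external imaging libraries, and a JPEG decoder is out of
#' scope. Convert JPEGs to PNG or TIFF before analysis.
#'
#' @param path Path to the image file. The format is detected from the file
#'   content (magic bytes), falling back to the extension.
#' @return A [raster_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", 8L)
  if (length(magic) >= 8L && identical(magic, PNG_SIGNATURE)) return(read_png(path))
  head2 <- rawToChar(magic[1:2])
  if (head2 %in% c("P5", "P6")) return(read_pnm(path))
  if (head2 %in% c("II", "MM")) return(read_tiff(path))
  if (length(magic) >= 2L && magic[1] == as.raw(0xff) && magic[2] == as.raw(0xd8))
    stop("JPEG input is not supported by this build; convert to PNG or TIFF first: ",
         path, call. = FALSE)
  stop("unrecognised image format: ", path, call. = FALSE)
}

#' Write a raster image
#'
#' Format is chosen from the file extension: `.png`, `.pgm`/`.ppm`/`.pnm`,
#' or `.tif`/`.tiff`. All supported formats are lossless: reading the file
#' back returns the identical pixel grid.
#'
#' @param img A [raster_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = write_png(img, path),
    pgm  = , ppm = , pnm = write_pnm(img, path),
    tif  = , tiff = write_tiff(img, path),
    stop("unsupported output format: .", ext,
         " (use .png, .pgm/.ppm, or .tif)", call. = FALSE)
  )
}
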