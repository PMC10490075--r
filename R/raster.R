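#' Raster image container
#'
#' An 8-bit raster: a `height x width` integer matrix (grayscale) or a
#' `height x width x 3` integer array with channels ordered (R, G, B).
#' Pixel coordinates are 1-based `(row, col)`, row-major; a pixel occupies
#' the unit square centred on its index.
#'
#' @param pixels Integer matrix (grayscale) or `h x w x 3` array (RGB) with
#'   all intensities in `[0, 255]`.
#' @return An object of class `raster_image` with fields `pixels`, `height`,
#'   `width`, `channels`.
#' @examples
#' img <- raster_image(matrix(0L, 10, 10))
#' img$channels
#' @export
raster_image <- function(pixels) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L) {
    channels <- 3L
  } else {
    stop("`pixels` must be a matrix (grayscale) or an h x w x 3 array (RGB)",
         call. = FALSE)
  }
  if (anyNA(pixels)) stop("pixel intensities must not contain NA", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  structure(
    list(pixels = pixels, height = d[1], width = d[2], channels = channels),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d, %d channel%s, intensities [%d, %d]\n",
              x$height, x$width, x$channels, if (x$channels > 1) "s" else "",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

stopifnot_gray <- function(img, what) {
  if (!is_raster_image(img)) stop(what, " expects a raster_image", call. = FALSE)
  if (img$channels != 1L)
    stop(what, " expects a 1-channel (grayscale) image; call to_grayscale() first",
         call. = FALSE)
}

#' Global threshold specification
#'
#' A fixed global threshold: pixels with intensity strictly greater than
#' `lower` become foreground with value `maxval`; all others become 0.
#' The defaults used by the pipeline are `threshold_spec(140, 255)` for seed
#' size traits and `threshold_spec(170, 255)` for projected area and
#' counting, the higher cutoff suppressing faint background noise.
#'
#' @param lower Integer cutoff in `[0, 255]`; strictly-greater comparison.
#' @param maxval Output value assigned to foreground, in `[1, 255]`.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(lower, maxval = 255L) {
  lower <- as.integer(lower); maxval <- as.integer(maxval)
  if (is.na(lower) || is.na(maxval) || lower < 0L || maxval > 255L || lower >= maxval)
    stop("threshold_spec requires 0 <= lower < maxval <= 255", call. = FALSE)
  structure(list(lower = lower, maxval = maxval), class = "threshold_spec")
}

#' Morphological dilation specification
#'
#' @param kernel_shape Side length of the square structuring element; odd
#'   integer `>= 1`.
#' @param iterations Number of dilation passes; `0` disables dilation.
#' @return A `morphology_spec` object.
#' @export
morphology_spec <- function(kernel_shape = 3L, iterations = 1L) {
  kernel_shape <- as.integer(kernel_shape); iterations <- as.integer(iterations)
  if (is.na(kernel_shape) || kernel_shape < 1L || kernel_shape %% 2L == 0L)
    stop("kernel_shape must be an odd integer >= 1", call. = FALSE)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be >= 0", call. = FALSE)
  structure(list(kernel_shape = kernel_shape, iterations = iterations),
            class = "morphology_spec")
}

#' Convert an image to grayscale
#'
#' RGB images are converted by ITU-R BT.601 luminance weighting
#' `0.299 R + 0.587 G + 0.114 B`, rounded half-up to an integer in
#' `[0, 255]`. Grayscale input is returned unchanged.
#'
#' @param img A [raster_image()].
#' @return A 1-channel `raster_image` of the same height and width.
#' @export
to_grayscale <- function(img) {
  if (!is_raster_image(img)) stop("to_grayscale expects a raster_image", call. = FALSE)
  if (img$channels == 1L) return(img)
  p <- img$pixels
  g <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  g <- floor(g + 0.5)   # round half-up, not banker's rounding
  raster_image(matrix(as.integer(g), img$height, img$width))
}

#' Morphological dilation of a grayscale image
#'
#' Replaces each pixel by the maximum intensity over a square neighbourhood,
#' repeated `spec$iterations` times. Dilation grows bright (foreground)
#' regions and is used before thresholding in the counting pipeline to
#' solidify seed silhouettes.
#'
#' @param img A 1-channel [raster_image()].
#' @param spec A [morphology_spec()].
#' @return The dilated `raster_image`.
#' @export
dilate <- function(img, spec = morphology_spec()) {
  stopifnot_gray(img, "dilate")
  if (!inherits(spec, "morphology_spec")) stop("spec must be a morphology_spec", call. = FALSE)
  if (spec$iterations == 0L || spec$kernel_shape == 1L) return(img)
  raster_image(.cpp_dilate(img$pixels, spec$kernel_shape, spec$iterations))
}

#' Binary mask produced by global thresholding
#'
#' @param pixels Integer matrix containing only `0` and `maxval`.
#' @param maxval The foreground value.
#' @return A `binary_mask` object with fields `pixels`, `height`, `width`,
#'   `maxval`.
#' @export
binary_mask <- function(pixels, maxval = 255L) {
  maxval <- as.integer(maxval)
  if (!is.matrix(pixels)) stop("mask pixels must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (!all(pixels == 0L | pixels == maxval))
    stop("a binary mask may contain only 0 and maxval", call. = FALSE)
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 maxval = maxval),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px (maxval %d)\n",
              x$height, x$width, sum(x$pixels > 0L), x$maxval))
  invisible(x)
}

#' Global binary thresholding
#'
#' Per-pixel binarisation: output is `spec$maxval` where the input intensity
#' is strictly greater than `spec$lower`, else `0`.
#'
#' @param img A 1-channel [raster_image()].
#' @param spec A [threshold_spec()].
#' @return A [binary_mask()] of the same dimensions.
#' @export
threshold <- function(img, spec) {
  stopifnot_gray(img, "threshold")
  if (!inherits(spec, "threshold_spec")) stop("spec must be a threshold_spec", call. = FALSE)
  out <- matrix(0L, img$height, img$width)
  out[img$pixels > spec$lower] <- spec$maxval
  binary_mask(out, spec$maxval)
}
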