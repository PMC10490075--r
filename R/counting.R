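#' Count seeds in an image
#'
#' The counting chain: grayscale conversion, dilation (default on — it
#' solidifies seed silhouettes before binarisation), thresholding with the
#' stricter area/counting cutoff (default 170/255), contour extraction, and
#' a count of contours at or above the noise floor.
#'
#' Touching or overlapping seeds merge into a single contour and are
#' counted as one — a documented limitation of the contour-count approach;
#' no declumping is attempted.
#'
#' @param img A [raster_image()].
#' @param cfg A [measure_config()]; `area_threshold`, `morphology`,
#'   `dilate_for_count`, and `min_contour_area_px` are used.
#' @return A `count_result` with fields `n_seeds`, `contour_areas_px`
#'   (retained areas, in scan order), and `n_rejected_noise` (regions below
#'   the noise floor).
#' @export
count_seeds <- function(img, cfg = measure_config()) {
  stopifnot(inherits(cfg, "measure_config"))
  g <- to_grayscale(img)
  if (cfg$dilate_for_count) g <- dilate(g, cfg$morphology)
  mask <- threshold(g, cfg$area_threshold)
  contours <- find_contours(mask)
  areas <- vapply(contours, function(ct) ct$area_px, numeric(1))
  keep <- areas >= cfg$min_contour_area_px
  structure(
    list(n_seeds = sum(keep),
         contour_areas_px = as.integer(areas[keep]),
         n_rejected_noise = sum(!keep)),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d seed%s (%d noise region%s rejected)\n",
              x$n_seeds, if (x$n_seeds == 1L) "" else "s",
              x$n_rejected_noise, if (x$n_rejected_noise == 1L) "" else "s"))
  invisible(x)
}
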